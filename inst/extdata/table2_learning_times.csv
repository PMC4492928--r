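list_id,interval,S1_seconds,S2_seconds,Q_printed
1,20 min,1405,670,0.523
2,20 min,1840,1210,0.342
3,20 min,1830,1100,0.399
4,20 min,2180,960,0.560
5,20 min,1800,840,0.533
6,20 min,1815,1345,0.259
7,20 min,2040,1110,0.456
8,20 min,1725,865,0.499
9,20 min,1935,1320,0.318
10,20 min,1830,1235,0.325
1,1 hour,1690,1280,0.243
2,1 hour,1790,1330,0.257
3,1 hour,2070,1235,0.403
4,1 hour,1875,1130,0.397
5,1 hour,1775,1245,0.299
6,1 hour,1765,1170,0.337
7,1 hour,1680,1125,0.330
8,1 hour,1905,1250,0.344
9,1 hour,1805,1155,0.360
10,1 hour,2065,1325,0.358
1,9 hours,1815,1240,0.317
2,9 hours,1780,1350,0.242
3,9 hours,1935,1350,0.302
4,9 hours,1525,975,0.361
5,9 hours,1770,1275,0.280
6,9 hours,1815,1335,0.264
7,9 hours,1635,1220,0.254
8,9 hours,1845,1380,0.252
9,9 hours,1950,1585,0.187
1,1 day,1670,1105,0.338
2,1 day,1840,1325,0.280
3,1 day,1930,1205,0.376
4,1 day,1740,1365,0.216
5,1 day,1875,1410,0.248
6,1 day,1710,1215,0.289
7,1 day,1905,1325,0.304
8,1 day,2095,1235,0.411
9,1 day,1860,1290,0.306
10,1 day,1980,1275,0.356
1,2 days,1710,1195,0.301
2,2 days,1635,1340,0.180
3,2 days,1950,1580,0.190
4,2 days,1935,1440,0.256
5,2 days,1830,1500,0.180
6,2 days,2130,1485,0.303
7,2 days,1890,1440,0.238
8,2 days,2085,1460,0.300
9,2 days,1740,1335,0.233
10,2 days,1695,1375,0.189
1,6 days,1780,1370,0.230
2,6 days,1605,1560,0.028
3,6 days,1870,1545,0.174
4,6 days,2020,1805,0.106
5,6 days,2090,1785,0.146
6,6 days,1740,1585,0.089
7,6 days,1710,1350,0.211
8,6 days,2025,1665,0.178
9,6 days,2100,1415,0.326
10,6 days,1890,1275,0.325
1,31 days,1480,1380,0.068
2,31 days,1680,1450,0.137
3,31 days,1770,1530,0.136
4,31 days,1440,1510,-0.049
5,31 days,1650,1760,-0.067
6,31 days,1890,1785,0.056
7,31 days,1815,1745,0.039
8,31 days,1910,1505,0.212
9,31 days,1490,1260,0.154
10,31 days,1710,1395,0.184
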