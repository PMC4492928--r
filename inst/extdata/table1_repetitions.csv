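interval,n,learning_mean,learning_sd,relearning_mean,relearning_sd
20 min,10,30.77,2.90,16.26,2.27
1 hour,10,30.64,2.28,19.22,1.56
9 hours,9,31.07,2.08,22.48,2.67
1 day,10,31.22,2.34,21.33,2.11
2 days,10,31.42,2.49,24.19,2.30
6 days,10,31.21,3.19,25.97,3.37
31 days,10,29.44,2.26,28.23,3.48
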