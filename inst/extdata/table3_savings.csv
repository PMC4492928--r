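subject,interval,savings
Ebbinghaus,20 min,0.582
Ebbinghaus,1 hour,0.442
Ebbinghaus,9 hours,0.358
Ebbinghaus,1 day,0.337
Ebbinghaus,2 days,0.278
Ebbinghaus,6 days,0.254
Ebbinghaus,31 days,0.211
Mack,20 min,0.544
Mack,1 hour,0.432
Mack,9 hours,0.285
Mack,1 day,0.316
Mack,2 days,0.365
Mack,6 days,0.309
Mack,31 days,0.258
Seitz,20 min,0.442
Seitz,1 hour,0.325
Seitz,9 hours,0.270
Seitz,1 day,0.270
Seitz,2 days,0.286
Seitz,6 days,0.205
Seitz,31 days,0.201
Dros,20 min,0.472
Dros,1 hour,0.373
Dros,9 hours,0.276
Dros,1 day,0.317
Dros,2 days,0.230
Dros,6 days,0.168
Dros,31 days,0.041
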