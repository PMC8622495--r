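cutoff,sensitivity,specificity,lr_pos,lr_neg
5,1.0000,0.0000,1.00,NA
6,0.9912,0.1818,1.21,0.05
7,0.9027,0.3182,1.32,0.31
8,0.6991,0.6818,2.20,0.44
9,0.4602,0.7273,1.69,0.74
10,0.3186,0.9545,7.01,0.71
11,0.1770,1.0000,NA,0.82
12,0.0531,1.0000,NA,0.95
13,0.0265,1.0000,NA,0.97
14,0.0088,1.0000,NA,0.99
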