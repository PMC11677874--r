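# Serum albumin relative to the healthy young adult (ratio = 1), by age.
# Linearly interpolated; package defaults.
age_y,albumin_ratio
2,0.93
5,0.95
8,0.97
12,0.99
18,1.00
40,1.00
60,0.97
80,0.93
100,0.90
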