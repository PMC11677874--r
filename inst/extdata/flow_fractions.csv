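# Regional blood flows as fractions of cardiac output (lung receives the
# whole cardiac output in series and is excluded).  liver_artery is the
# hepatic arterial supply; gut, spleen and stomach drain into the portal
# vein.  'rest' is the residual perfusion; rows are renormalized to sum to
# exactly 1 when loaded.  Package defaults, literature-informed.
sex,age_y,brain,heart,kidney,liver_artery,gut,spleen,stomach,muscle,skin,adipose,bone,gonads,rest
male,2,0.300,0.040,0.160,0.060,0.140,0.028,0.009,0.080,0.050,0.030,0.040,0.0002,0.0628
male,5,0.250,0.040,0.170,0.062,0.145,0.029,0.009,0.100,0.050,0.035,0.043,0.0002,0.0668
male,8,0.200,0.040,0.175,0.063,0.148,0.029,0.010,0.120,0.050,0.040,0.045,0.0002,0.0798
male,12,0.160,0.040,0.180,0.064,0.150,0.030,0.010,0.140,0.050,0.045,0.047,0.0003,0.0837
male,15,0.140,0.040,0.185,0.064,0.150,0.030,0.010,0.155,0.050,0.048,0.049,0.0004,0.0786
male,18,0.125,0.040,0.188,0.065,0.150,0.030,0.010,0.165,0.050,0.050,0.050,0.0005,0.0765
male,30,0.120,0.040,0.190,0.065,0.150,0.030,0.010,0.170,0.050,0.050,0.050,0.0005,0.0745
male,45,0.120,0.040,0.185,0.065,0.150,0.030,0.010,0.165,0.050,0.055,0.050,0.0005,0.0795
male,70,0.120,0.045,0.170,0.065,0.150,0.030,0.010,0.155,0.050,0.060,0.050,0.0005,0.0945
male,100,0.120,0.045,0.160,0.065,0.150,0.030,0.010,0.150,0.050,0.060,0.050,0.0005,0.1095
female,2,0.300,0.040,0.155,0.060,0.140,0.028,0.009,0.075,0.050,0.035,0.040,0.0002,0.0678
female,5,0.250,0.040,0.165,0.062,0.145,0.029,0.009,0.090,0.050,0.040,0.043,0.0002,0.0768
female,8,0.200,0.040,0.170,0.063,0.148,0.029,0.010,0.110,0.050,0.045,0.045,0.0002,0.0898
female,12,0.160,0.040,0.172,0.064,0.150,0.030,0.010,0.125,0.050,0.055,0.047,0.0002,0.0968
female,15,0.140,0.040,0.174,0.064,0.150,0.030,0.010,0.130,0.050,0.070,0.049,0.0002,0.0928
female,18,0.128,0.040,0.175,0.065,0.150,0.030,0.010,0.135,0.050,0.083,0.050,0.0002,0.0838
female,30,0.125,0.040,0.175,0.065,0.150,0.030,0.010,0.140,0.050,0.085,0.050,0.0002,0.0798
female,45,0.125,0.040,0.172,0.065,0.150,0.030,0.010,0.135,0.050,0.088,0.050,0.0002,0.0848
female,70,0.125,0.045,0.160,0.065,0.150,0.030,0.010,0.125,0.050,0.090,0.050,0.0002,0.0998
female,100,0.125,0.045,0.150,0.065,0.150,0.030,0.010,0.120,0.050,0.090,0.050,0.0002,0.1148
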