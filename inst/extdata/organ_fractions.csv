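# Organ volumes as fractions of body weight (density ~1 kg/L assumed),
# by age and sex.  Package defaults assembled from ICRP-style reference
# anatomy; interpolated linearly in age.  The residual body mass not listed
# here forms the 'rest' compartment.
sex,age_y,lung,brain,heart,kidney,liver,gut,spleen,stomach,muscle,skin,adipose,bone,gonads,arterial_blood,venous_blood
male,2,0.0072,0.0840,0.0048,0.0074,0.0340,0.0160,0.0024,0.0024,0.2500,0.0580,0.2100,0.1100,0.0002,0.0250,0.0500
male,5,0.0070,0.0650,0.0047,0.0065,0.0320,0.0150,0.0023,0.0023,0.3000,0.0520,0.1700,0.1150,0.0002,0.0245,0.0490
male,8,0.0069,0.0480,0.0046,0.0058,0.0300,0.0145,0.0022,0.0022,0.3300,0.0500,0.1600,0.1200,0.0002,0.0240,0.0480
male,12,0.0068,0.0330,0.0045,0.0050,0.0280,0.0140,0.0022,0.0021,0.3500,0.0480,0.1700,0.1300,0.0003,0.0240,0.0480
male,15,0.0068,0.0260,0.0045,0.0046,0.0260,0.0138,0.0021,0.0021,0.3800,0.0470,0.1700,0.1350,0.0004,0.0245,0.0485
male,18,0.0068,0.0220,0.0045,0.0043,0.0250,0.0138,0.0021,0.0021,0.3950,0.0460,0.1850,0.1400,0.0005,0.0247,0.0490
male,30,0.0068,0.0199,0.0045,0.0042,0.0247,0.0137,0.0021,0.0021,0.3970,0.0450,0.1990,0.1440,0.0005,0.0247,0.0479
male,45,0.0068,0.0192,0.0046,0.0041,0.0240,0.0137,0.0021,0.0021,0.3800,0.0450,0.2200,0.1420,0.0005,0.0247,0.0479
male,70,0.0068,0.0188,0.0047,0.0038,0.0220,0.0137,0.0021,0.0021,0.3450,0.0450,0.2450,0.1350,0.0005,0.0247,0.0479
male,100,0.0068,0.0185,0.0047,0.0036,0.0210,0.0137,0.0021,0.0021,0.3200,0.0450,0.2500,0.1300,0.0005,0.0247,0.0479
female,2,0.0072,0.0850,0.0047,0.0073,0.0335,0.0160,0.0024,0.0024,0.2450,0.0580,0.2150,0.1080,0.0002,0.0250,0.0500
female,5,0.0070,0.0660,0.0046,0.0064,0.0315,0.0150,0.0023,0.0023,0.2900,0.0520,0.1800,0.1120,0.0002,0.0243,0.0487
female,8,0.0069,0.0490,0.0045,0.0057,0.0295,0.0148,0.0022,0.0022,0.3100,0.0500,0.1850,0.1150,0.0002,0.0240,0.0480
female,12,0.0068,0.0330,0.0044,0.0050,0.0280,0.0145,0.0022,0.0021,0.3200,0.0480,0.2100,0.1180,0.0002,0.0238,0.0476
female,15,0.0068,0.0270,0.0043,0.0047,0.0265,0.0143,0.0022,0.0021,0.3100,0.0470,0.2500,0.1200,0.0002,0.0235,0.0470
female,18,0.0068,0.0235,0.0042,0.0046,0.0240,0.0160,0.0022,0.0023,0.3000,0.0450,0.2800,0.1250,0.0002,0.0233,0.0467
female,30,0.0068,0.0217,0.0042,0.0046,0.0233,0.0160,0.0022,0.0023,0.2920,0.0450,0.3000,0.1300,0.0002,0.0233,0.0450
female,45,0.0068,0.0210,0.0043,0.0045,0.0230,0.0160,0.0022,0.0023,0.2800,0.0450,0.3200,0.1280,0.0002,0.0233,0.0450
female,70,0.0068,0.0205,0.0044,0.0042,0.0215,0.0160,0.0022,0.0023,0.2550,0.0450,0.3400,0.1200,0.0002,0.0233,0.0450
female,100,0.0068,0.0200,0.0044,0.0040,0.0205,0.0160,0.0022,0.0023,0.2400,0.0450,0.3450,0.1150,0.0002,0.0233,0.0450
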