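# Physiology modifiers for impairment scenarios (package defaults, editable).
# CKD stages scale glomerular filtration; end-stage disease additionally
# carries hypoalbuminemia.  Child-Pugh grades follow the published
# cirrhosis-scaler convention: reduced hepatic enzyme expression, reduced
# hepatic blood flow, hypoalbuminemia, and increasing portosystemic shunt.
name,gfr_multiplier,albumin_multiplier,hepatic_flow_multiplier,shunt_fraction,cyp1a2,cyp2c9,cyp2c19,cyp2d6
healthy,1,1,1,0,1,1,1,1
ckd3,0.50,1.00,1,0,1,1,1,1
ckd4,0.25,0.95,1,0,1,1,1,1
ckd5,0.08,0.80,1,0,1,1,1,1
cp_a,1.00,0.90,0.85,0.15,0.7,0.7,0.7,0.7
cp_b,0.90,0.75,0.70,0.35,0.5,0.5,0.5,0.5
cp_c,0.75,0.60,0.55,0.55,0.3,0.3,0.3,0.3
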