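# Transcribed predicted/observed PK summaries for the twelve verification
# profiles (source-study NCA values).  cl units are L/h, except per-kg-dosed
# pediatric rows where they are L/h/kg (per_kg = TRUE).
design_id,population,dose_label,route,per_kg,cmax_pre,cmax_obs,auc_pre,auc_obs,cl_pre,cl_obs
iv50_young,young_adult,50 mg,iv_bolus,FALSE,150.54,251.1,841.09,565.97,59.44,88.34
po25_young_men,young_adult,25 mg (men),po,FALSE,22.95,29.65,191.45,190.25,130.58,131.4
po25_young_women,young_adult,25 mg (women),po,FALSE,29.75,30.28,256.4,212.39,97.5,117.7
po50_young,young_adult,50 mg,po,FALSE,51,68.42,484.36,507.32,103.22,98.55
po87.9_young,young_adult,87.9 mg,po,FALSE,83.44,101.62,828.82,1131.12,106.05,77.71
po25_elderly_men,elderly,25 mg (men),po,FALSE,24.17,22.45,209.02,214.22,119.6,116.69
po25_elderly_women,elderly,25 mg (women),po,FALSE,28.04,23.19,275.78,188.08,90.64,132.92
po86_elderly,elderly,86 mg,po,FALSE,82.28,165.02,917.97,1827.5,93.68,47.05
po0.556_children,pediatric,0.556 mg/kg,po,TRUE,44.32,44.14,339.38,329.31,1.73,1.79
po0.807_children,pediatric,0.807 mg/kg,po,TRUE,67.52,74.52,525.04,580.4,1.54,1.39
po1.25_children,pediatric,1.25 mg/kg,po,TRUE,94.95,81.16,823.91,467.25,1.51,2.67
po0.93_adolescent,pediatric,0.930 mg/kg,po,TRUE,74.16,89.1,649.49,839.07,1.39,1.07
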