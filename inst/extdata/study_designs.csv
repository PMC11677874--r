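# Clinical study designs used for model building and verification: cohort
# demographics, dose and route for the twelve concentration-time profiles.
# Sampling times are not printed in the source summaries and are package
# defaults; the intravenous-bolus design starts sampling at 1 h because the
# observed peak implies a distribution volume near 200 L, i.e. the first
# sample postdates the distribution phase.  female_pct 56.25 is stored
# verbatim from the source table (ambiguous entry).  Weights NA: defaults
# interpolated from the growth table.
design_id,population,cohort,age_min_y,age_max_y,female_pct,weight_min_kg,weight_max_kg,dose,dose_unit,route,formulation,sampling_times_h
iv50_young,young_adult,Young adults,26,41,40,NA,NA,50,mg,iv_bolus,solution,1;1.5;2;3;4;6;8;12;24
po25_young_men,young_adult,Young men,24.6,36.2,0,71.7,76.1,25,mg,po,lint80,0.25;0.5;0.75;1;1.5;2;3;4;6;8;12;24
po25_young_women,young_adult,Young women,27,31.8,100,56.7,74.1,25,mg,po,lint80,0.25;0.5;0.75;1;1.5;2;3;4;6;8;12;24
po50_young,young_adult,Young adults,26,41,40,NA,NA,50,mg,po,lint80,0.25;0.5;0.75;1;1.5;2;3;4;6;8;12;24
po87.9_young,young_adult,Young adults,21.1,41.9,50,60.4,80.2,87.9,mg,po,lint80,0.25;0.5;0.75;1;1.5;2;3;4;6;8;12;24
po25_elderly_men,elderly,Elderly men,62.5,66.1,0,66.5,77.3,25,mg,po,lint80,0.25;0.5;0.75;1;1.5;2;3;4;6;8;12;24
po25_elderly_women,elderly,Elderly women,68.9,71.3,100,65.6,72.8,25,mg,po,lint80,0.25;0.5;0.75;1;1.5;2;3;4;6;8;12;24
po86_elderly,elderly,Elderly adults,65.1,73.7,50,59.6,82.4,86,mg,po,lint80,0.25;0.5;0.75;1;1.5;2;3;4;6;8;12;24
po0.556_children,pediatric,Children 2-5 y,2.76,4.84,38,13.7,20.9,0.556,mg_kg,po,lint80,0.25;0.5;0.75;1;1.5;2;3;4;6;8;12;24
po0.807_children,pediatric,Children 6-10 y,6.61,9.99,56.25,23.14,36.66,0.807,mg_kg,po,lint80,0.25;0.5;0.75;1;1.5;2;3;4;6;8;12;24
po1.25_children,pediatric,Children 7-11 y,7.2,10.6,50,24.8,38.4,1.25,mg_kg,po,lint80,0.25;0.5;0.75;1;1.5;2;3;4;6;8;12;24
po0.93_adolescent,pediatric,Adolescents,12.75,16.45,50,46.24,64.36,0.93,mg_kg,po,lint80,0.25;0.5;0.75;1;1.5;2;3;4;6;8;12;24
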