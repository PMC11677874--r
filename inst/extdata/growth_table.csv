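# Reference body weight and height by age and sex (package defaults,
# literature-informed growth-reference medians; linearly interpolated in age).
sex,age_y,weight_kg,height_cm
male,2,12.5,87
male,5,19,110
male,8,26,128
male,12,40,149
male,15,56,169
male,18,68,176
male,30,73,176
male,45,76,176
male,70,74,174
male,100,70,171
female,2,12,86
female,5,18,109
female,8,25.5,127
female,12,42,151
female,15,53,161
female,18,58,163
female,30,60,163
female,45,64,162
female,70,62,159
female,100,58,156
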