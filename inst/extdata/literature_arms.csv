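name,n,or_minutes,or_minutes_sd,surgery_prob,use_navigation,material_key,icu_days,icu_days_sd,stroke_unit_days,ward_days,ward_days_sd,rehab_discharge_frac,mortality_30d_n,mrs0,mrs1,mrs2,mrs3,mrs4,mrs5,mrs6,los_icu_median,los_hospital_median
mistie3_intervention,255,60,0,1,TRUE,mistie_catheter,10,2.5,0,45,17.75,,24,1,15,30,64,60,31,48,10,55
kellner_intervention,100,150,66,1,TRUE,endoscope_consumables,8.5,2.25,0,8.5,3.75,0.93,9,1,9,19,17,25,13,16,9,17
mistie3_candidates_conventional,17,130,63,0.29411764705882354,FALSE,,4,8.8,2,18,41.6,0.706,4,0,0,0,2,2,3,7,4,24
dist_candidates_conventional,59,136.9,72,0.16949152542372881,FALSE,,4,11.5,2.5,16,24.6,0.559,14,2,1,5,6,10,6,19,4,23
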