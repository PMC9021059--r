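study,source_table,endpoint,tissue,d1_gy,d2_gy,dt_h,t_h,n2_events,n2_denom,n12_events,n12_denom,delta,footnote
Shadley & Dai,Table I,chromosome_aberrations,lymphocytes,0.05,2,6,30,95,100,48,100,0.495,c
Shadley & Dai,Table I,chromosome_aberrations,lymphocytes,0.05,4,6,30,188,100,143,100,0.239,c
Shadley & Dai,Table I,chromosome_aberrations,lymphocytes,0.05,2,6,30,90,100,74,100,0.178,c
Shadley & Dai,Table I,chromosome_aberrations,lymphocytes,0.05,4,6,30,240,100,166,100,0.308,c
Shadley & Dai,Table I,chromosome_aberrations,lymphocytes,0.05,2,6,30,69,100,55,100,0.203,c
Shadley & Dai,Table I,chromosome_aberrations,lymphocytes,0.05,4,6,30,118,100,65,100,0.449,c
Shadley & Dai,Table I,chromosome_aberrations,lymphocytes,0.05,2,6,30,106,100,87,100,0.179,c
Shadley & Dai,Table I,chromosome_aberrations,lymphocytes,0.05,4,6,30,218,100,176,100,0.193,c
Shadley & Dai,Table I,chromosome_aberrations,lymphocytes,0.05,2,6,30,58,100,51,100,0.121,c
Shadley & Dai,Table I,chromosome_aberrations,lymphocytes,0.05,4,6,30,192,100,147,100,0.234,c
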