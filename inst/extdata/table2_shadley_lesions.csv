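study,source_table,endpoint,tissue,d1_gy,d2_gy,dt_h,t_h,n2_events,n2_denom,n12_events,n12_denom,delta,footnote
Shadley & Wolff,Table II,chromatid_breaks,lymphocytes,0.01,1.5,16,22,83,200,60,200,0.277,b
Shadley & Wolff,Table II,chromatid_breaks,lymphocytes,0.05,1.5,16,22,83,200,58,200,0.301,b
Shadley & Wolff,Table II,chromatid_breaks,lymphocytes,0.1,1.5,16,22,83,200,66,200,0.205,b
Shadley & Wolff,Table II,chromatid_breaks,lymphocytes,0.2,1.5,16,22,83,200,83,200,0.000,b
Shadley & Wolff,Table II,chromatid_breaks,lymphocytes,0.3,1.5,16,22,83,200,99,200,-0.193,"b,d"
Shadley & Wolff,Table II,chromatid_breaks,lymphocytes,0.4,1.5,16,22,83,200,103,200,-0.241,"b,d"
Shadley & Wolff,Table II,chromatid_breaks,lymphocytes,0.5,1.5,16,22,83,200,126,200,-0.518,"b,d"
Shadley et al.,Table I,chromatid_breaks,lymphocytes,0.01,1.5,44,50,101,300,78,300,0.228,b
Shadley et al.,Table I,chromatid_breaks,lymphocytes,0.01,1.5,40,46,101,300,73,300,0.277,b
Shadley et al.,Table I,chromatid_breaks,lymphocytes,0.01,1.5,36,42,101,300,68,300,0.327,b
Shadley et al.,Table I,chromatid_breaks,lymphocytes,0.01,1.5,34,40,101,300,73,300,0.277,b
Shadley et al.,Table II,chromatid_breaks,lymphocytes,0.01,1.5,34,40,68,200,48,200,0.294,b
Shadley et al.,Table II,chromatid_breaks,lymphocytes,0.01,1.5,32,38,68,200,51,200,0.250,b
Shadley et al.,Table II,chromatid_breaks,lymphocytes,0.01,1.5,30,36,68,200,49,200,0.279,b
Shadley et al.,Table II,chromatid_breaks,lymphocytes,0.01,1.5,28,34,68,200,47,200,0.309,b
Shadley et al.,Table II,chromatid_breaks,lymphocytes,0.01,1.5,10,16,68,200,42,200,0.382,b
Shadley et al.,Table III,chromatid_breaks,lymphocytes,0.01,1.5,14,20,68,200,40,200,0.412,b
Shadley et al.,Table III,chromatid_breaks,lymphocytes,0.01,1.5,20,26,76,200,43,200,0.434,b
Shadley et al.,Table III,chromatid_breaks,lymphocytes,0.01,1.5,38,44,71,200,36,200,0.493,b
Shadley et al.,Table IV,chromatid_breaks,lymphocytes,0.01,1.5,18,24,84,200,55,200,0.345,b
Shadley et al.,Table IV,chromatid_breaks,lymphocytes,0.01,1.5,36,42,92,200,55,200,0.402,b
Shadley et al.,Table IV,chromatid_breaks,lymphocytes,0.01,1.5,60,66,88,200,83,200,0.057,b
Shadley et al.,Table IV,chromatid_breaks,lymphocytes,0.01,1.5,84,90,93,200,88,200,0.054,b
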