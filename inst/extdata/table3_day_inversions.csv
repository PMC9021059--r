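study,source_table,endpoint,tissue,d1_gy,d2_gy,dt_h,t_h,n2_events,n2_denom,n12_events,n12_denom,delta,footnote
Day et al. (study 1),Table,chromosomal_inversions,prostate,1e-06,1,4,72,0.00572,1,0.00093,1,0.837,
Day et al. (study 1),Table,chromosomal_inversions,prostate,1e-05,1,4,72,0.00572,1,0.0017,1,0.703,
Day et al. (study 1),Table,chromosomal_inversions,prostate,0.001,1,4,72,0.00572,1,0.00188,1,0.671,
Day et al. (study 1),Table,chromosomal_inversions,prostate,0.01,1,4,72,0.00572,1,0.00098,1,0.829,
Day et al. (study 2),Table,chromosomal_inversions,prostate,1e-05,1,4,72,0.00466,1,0.00088,1,0.811,
Day et al. (study 2),Table,chromosomal_inversions,prostate,0.01,1,4,72,0.00466,1,0.00113,1,0.758,
Day et al. (study 2),Table,chromosomal_inversions,spleen,1e-05,1,4,72,0.00315,1,0.00077,1,0.756,
Day et al. (study 2),Table,chromosomal_inversions,spleen,0.01,1,4,72,0.00315,1,0.00098,1,0.689,
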