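sample_id,patient,x,r,ihc_score,her2_signals,cep17_signals,n_cells,published_area,published_dish_ratio,published_ba,published_b_prime
case_01,1,0.341,1.39,2+,261,57,20,Equivocal,4.58,1.92,3.96
case_44,32,0.264,1.49,3+,158,60,20,Equivocal,2.63,2.40,4.47
case_08,7,0.087,1.10,2+,106,79,20,Equivocal,1.34,1.63,4.35
case_15,13,0.330,1.36,1+,102,55,20,Equivocal,1.86,1.89,3.74
case_32,24,0.297,1.35,2+,64,52,20,Equivocal,1.23,1.99,3.51
case_41,29,0.305,1.55,2+,132,87,20,Equivocal,1.52,2.13,6.75
case_33,24,0.531,1.95,2+,65,62,20,Positive,1.05,2.49,6.05
case_29,24,0.517,2.38,2+,111,48,20,Positive,2.31,3.45,5.71
case_25,21,0.414,28.25,3+,420,64,20,Positive,6.56,52.36,90.4
case_26,21,0.390,19.99,3+,420,63,20,Positive,6.67,38.85,62.97
case_42,30,0.283,24.00,3+,420,59,20,Positive,7.12,63.51,70.80
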