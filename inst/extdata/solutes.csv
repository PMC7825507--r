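name,class,Z,D_inf_cm2_s,Smax_umol_g,Ks,kd_per_hr,Ccyto_umol_cm3,P_cm_hr,Imax_umol_cm_hr,KI_umol_cm3
glucose,sugar,0,6.7e-6,2.39,0.5,0.45,44.7,,0.0297,0.1086278
glycine,amino_acid,0,1.06e-5,1.0,0.3,2.0,5.0,,0.02,0.05
tartarate,organic_acid,-2,5.2e-6,8.0,1.5,0.8,59.5,,0,0
malate,organic_acid,-2,7.58e-6,6.0,1.0,0.9,27.4,,0,0
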