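route,dose_tfds_mgkg,dose_schaftoside_mgkg,cmax_mean,cmax_sd,tmax_median,tmax_lo,tmax_hi,auc_last_mean,auc_last_sd,t_half_mean,t_half_sd,vz_f_mean,vz_f_sd,cl_f_mean,cl_f_sd
iv,NA,1.2,5567.22,1007.46,NA,NA,NA,2776.8,449.16,0.64,0.1,0.41,0.1,0.44,0.07
oral,50,3.03,23.17,5.07,0.5,0.25,1.5,76.39,20.26,2.22,0.47,132.72,26.39,39,9.76
oral,100,6.06,46.25,15.94,1,0.5,1.5,204.75,59.5,2.18,0.53,114.7,44.07,30.22,9.87
oral,200,12.12,91.75,18.59,1.25,0.5,1.5,357.09,123.71,2.03,0.09,105.42,29.09,35.86,9.31
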