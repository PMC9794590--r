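variable,unit,day1_mean,day1_sd,day1_lo,day1_hi,day6_mean,day6_sd,day6_lo,day6_hi
cmax,ng/mL,2.43,1,NA,NA,4.32,3.54,NA,NA
tmax,h,1.25,NA,1,1.5,1.5,NA,1,2
auc_last,h*ng/mL,13.19,4.16,NA,NA,15.62,5.77,NA,NA
t_half,h,1.62,0.21,NA,NA,2.41,0.86,NA,NA
cl_f,L/h,2048,655,NA,NA,NA,NA,NA,NA
vz_f,L,4740,1530,NA,NA,NA,NA,NA,NA
vss,L,NA,NA,NA,NA,6845,2668,NA,NA
cavg,ng/mL,NA,NA,NA,NA,1.69,0.65,NA,NA
auc_tau,h*ng/mL,NA,NA,NA,NA,13.55,5.19,NA,NA
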