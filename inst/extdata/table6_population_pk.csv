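population,parameter,stat,day,value
healthy_0p6,cmax,mean,1,2.76
healthy_1p0,cmax,mean,1,4.6
ckd3_0p6,cmax,mean,1,3.06
ckd4_0p6,cmax,mean,1,2.72
ckd5_0p6,cmax,mean,1,2.52
elderly_0p6,cmax,mean,1,2.86
healthy_0p6,cmax,p2.5,1,1.81
healthy_1p0,cmax,p2.5,1,3.02
ckd3_0p6,cmax,p2.5,1,2.32
ckd4_0p6,cmax,p2.5,1,1.93
ckd5_0p6,cmax,p2.5,1,1.89
elderly_0p6,cmax,p2.5,1,1.94
healthy_0p6,cmax,p97.5,1,3.91
healthy_1p0,cmax,p97.5,1,6.52
ckd3_0p6,cmax,p97.5,1,4.39
ckd4_0p6,cmax,p97.5,1,3.82
ckd5_0p6,cmax,p97.5,1,3.49
elderly_0p6,cmax,p97.5,1,3.96
healthy_0p6,cmax,mean,6,3.49
healthy_1p0,cmax,mean,6,5.82
ckd3_0p6,cmax,mean,6,6
ckd4_0p6,cmax,mean,6,12.65
ckd5_0p6,cmax,mean,6,20.64
elderly_0p6,cmax,mean,6,3.62
healthy_0p6,cmax,p2.5,6,2.25
healthy_1p0,cmax,p2.5,6,3.75
ckd3_0p6,cmax,p2.5,6,4.27
ckd4_0p6,cmax,p2.5,6,8.38
ckd5_0p6,cmax,p2.5,6,14.7
elderly_0p6,cmax,p2.5,6,2.5
healthy_0p6,cmax,p97.5,6,5.44
healthy_1p0,cmax,p97.5,6,9.07
ckd3_0p6,cmax,p97.5,6,9.76
ckd4_0p6,cmax,p97.5,6,22.49
ckd5_0p6,cmax,p97.5,6,29.38
elderly_0p6,cmax,p97.5,6,5.17
healthy_0p6,r_cmax,mean,NA,1.26
healthy_1p0,r_cmax,mean,NA,1.27
ckd3_0p6,r_cmax,mean,NA,1.96
ckd4_0p6,r_cmax,mean,NA,4.65
ckd5_0p6,r_cmax,mean,NA,8.19
elderly_0p6,r_cmax,mean,NA,1.27
healthy_0p6,r_cmax,p2.5,NA,1.24
healthy_1p0,r_cmax,p2.5,NA,1.24
ckd3_0p6,r_cmax,p2.5,NA,1.84
ckd4_0p6,r_cmax,p2.5,NA,4.34
ckd5_0p6,r_cmax,p2.5,NA,7.78
elderly_0p6,r_cmax,p2.5,NA,1.29
healthy_0p6,r_cmax,p97.5,NA,1.39
healthy_1p0,r_cmax,p97.5,NA,1.39
ckd3_0p6,r_cmax,p97.5,NA,2.22
ckd4_0p6,r_cmax,p97.5,NA,5.89
ckd5_0p6,r_cmax,p97.5,NA,8.42
elderly_0p6,r_cmax,p97.5,NA,1.3
healthy_0p6,auc_last,mean,1,13.33
healthy_1p0,auc_last,mean,1,22.22
ckd3_0p6,auc_last,mean,1,28.49
ckd4_0p6,auc_last,mean,1,46.31
ckd5_0p6,auc_last,mean,1,53.54
elderly_0p6,auc_last,mean,1,13.71
healthy_0p6,auc_last,p2.5,1,7.69
healthy_1p0,auc_last,p2.5,1,12.81
ckd3_0p6,auc_last,p2.5,1,18.5
ckd4_0p6,auc_last,p2.5,1,34.39
ckd5_0p6,auc_last,p2.5,1,40.5
elderly_0p6,auc_last,p2.5,1,7.74
healthy_0p6,auc_last,p97.5,1,22.05
healthy_1p0,auc_last,p97.5,1,36.75
ckd3_0p6,auc_last,p97.5,1,44.21
ckd4_0p6,auc_last,p97.5,1,60.96
ckd5_0p6,auc_last,p97.5,1,69.65
elderly_0p6,auc_last,p97.5,1,23.02
healthy_0p6,auc_last,mean,6,18.25
healthy_1p0,auc_last,mean,6,30.42
ckd3_0p6,auc_last,mean,6,62.21
ckd4_0p6,auc_last,mean,6,224.85
ckd5_0p6,auc_last,mean,6,433.77
elderly_0p6,auc_last,mean,6,18.98
healthy_0p6,auc_last,p2.5,6,9.35
healthy_1p0,auc_last,p2.5,6,15.59
ckd3_0p6,auc_last,p2.5,6,30.79
ckd4_0p6,auc_last,p2.5,6,128.03
ckd5_0p6,auc_last,p2.5,6,296.5
elderly_0p6,auc_last,p2.5,6,9.45
healthy_0p6,auc_last,p97.5,6,34.91
healthy_1p0,auc_last,p97.5,6,58.19
ckd3_0p6,auc_last,p97.5,6,133.06
ckd4_0p6,auc_last,p97.5,6,451.02
ckd5_0p6,auc_last,p97.5,6,647.54
elderly_0p6,auc_last,p97.5,6,39.48
healthy_0p6,r_auc,mean,NA,1.37
healthy_1p0,r_auc,mean,NA,1.37
ckd3_0p6,r_auc,mean,NA,2.18
ckd4_0p6,r_auc,mean,NA,4.86
ckd5_0p6,r_auc,mean,NA,8.1
elderly_0p6,r_auc,mean,NA,1.38
healthy_0p6,r_auc,p2.5,NA,1.22
healthy_1p0,r_auc,p2.5,NA,1.22
ckd3_0p6,r_auc,p2.5,NA,1.66
ckd4_0p6,r_auc,p2.5,NA,3.72
ckd5_0p6,r_auc,p2.5,NA,7.32
elderly_0p6,r_auc,p2.5,NA,1.22
healthy_0p6,r_auc,p97.5,NA,1.58
healthy_1p0,r_auc,p97.5,NA,1.58
ckd3_0p6,r_auc,p97.5,NA,3.01
ckd4_0p6,r_auc,p97.5,NA,7.4
ckd5_0p6,r_auc,p97.5,NA,9.3
elderly_0p6,r_auc,p97.5,NA,1.72
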