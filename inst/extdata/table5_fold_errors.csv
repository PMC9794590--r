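group,metric,observed,predicted,fe
iv_1p2,cmax,5567.22,5230.7,0.94
iv_1p2,auc_last,2776.8,4587.42,1.65
po_50,cmax,23.17,26.69,1.15
po_50,auc_last,76.39,89.09,1.17
po_100,cmax,46.25,53.41,1.15
po_100,auc_last,204.75,178.26,0.87
po_200,cmax,91.75,106.64,1.16
po_200,auc_last,357.09,356.62,1
po_100_literature,cmax,43.86,61.72,1.41
po_100_literature,auc_last,127.56,201.76,1.58
po_50,afe,NA,NA,1.03
po_100,afe,NA,NA,0.86
po_200,afe,NA,NA,1.02
po_100_literature,afe,NA,NA,1.51
po_50,aafe,NA,NA,1.35
po_100,aafe,NA,NA,1.47
po_200,aafe,NA,NA,1.33
po_100_literature,aafe,NA,NA,1.64
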