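stage,gfr,kidney_volume_fraction,renal_perfusion_fraction,fu_fraction,gastric_emptying_fraction,small_intestinal_transit_fraction,large_intestinal_transit_fraction
healthy,110.57,1,1,1,1,1,1
CKD3,60,0.81,0.55,1.07,1,1,1
CKD4,30,0.61,0.36,1.16,1.6,1.4,1
CKD5,15,0.51,0.29,1.55,1.6,1.4,1
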