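parameter,species,value,unit
mwt,both,596.494,g/mol
logp,both,-2.427,
acidic_pka,both,6.35,
solubility_ph7,both,0.02,g/L
fu,both,0.2665,
intestinal_permeability,both,1.08e-4,dm/min
organ_permeability,both,2.98e-6,cm/s
kidney_plasma_clearance,rat,0.00257,L/min/kg
dissolution_t50,rat,0.92,min
dissolution_shape,rat,0.00108,
kidney_plasma_clearance,human,0.00124,L/min/kg
dissolution_t50,human,8.16,min
dissolution_shape,human,3.74e-4,
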