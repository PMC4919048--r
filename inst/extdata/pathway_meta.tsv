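name	label	enzyme_count	electron_donors	carbon_species	knockouts	end_product	n_carbons_per_product
calvin	Calvin cycle	12	NADH	CO2		pyr_c	3
rtca	rTCA cycle	8	ferredoxin_red;NADPH;NADH	CO2		pyr_c	3
hp4hb	3HP-4HB cycle	13	NADPH;NADH	HCO3-	SUCOAS	pyr_c	3
dc4hb	DC-4HB cycle	14	ferredoxin_red;NADPH	CO2;HCO3-		pyr_c	3
pyrs_pyrc_glx	PyrS-PyrC-Glx bicycle	10	ferredoxin_red;NADH	CO2;HCO3-		pyr_c	3
pyrs_pepc_glx	PyrS-PEPC-Glx bicycle	11	ferredoxin_red;NADH	CO2;HCO3-		pyr_c	3
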