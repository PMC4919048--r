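id	name	compartment	formula
e_e	Extracellular electron	e	X
fdxox_c	Oxidized ferredoxin	c	Fe8S8X
fdxrd_c	Reduced ferredoxin	c	Fe8S8X
hco3_c	Bicarbonate	c	CHO3
ppi_c	Diphosphate	c	HO7P2
rb15bp_c	D-Ribulose 1,5-bisphosphate	c	C5H8O11P2
s17bp_c	Sedoheptulose 1,7-bisphosphate	c	C7H12O13P2
malcoa_c	Malonyl-CoA	c	C24H33N7O19P3S
hpp_c	3-Hydroxypropanoate	c	C3H5O3
ppcoa_c	Propanoyl-CoA	c	C24H35N7O17P3S
mmcoa_c	(S)-Methylmalonyl-CoA	c	C25H35N7O19P3S
mmcoar_c	(R)-Methylmalonyl-CoA	c	C25H35N7O19P3S
sucsal_c	Succinic semialdehyde	c	C4H5O3
ghb_c	4-Hydroxybutanoate	c	C4H7O3
4hbcoa_c	4-Hydroxybutyryl-CoA	c	C25H39N7O18P3S
b2coa_c	Crotonyl-CoA	c	C25H37N7O17P3S
3hbcoa_c	(S)-3-Hydroxybutyryl-CoA	c	C25H39N7O18P3S
aacoa_c	Acetoacetyl-CoA	c	C25H36N7O18P3S
mlycoa_c	(S)-Malyl-CoA	c	C25H35N7O20P3S
glx_c	Glyoxylate	c	C2HO3
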