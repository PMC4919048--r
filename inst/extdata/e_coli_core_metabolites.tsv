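id	name	compartment	formula
13dpg_c	3-Phospho-D-glyceroyl phosphate	c	C3H4O10P2
2pg_c	D-Glycerate 2-phosphate	c	C3H4O7P
3pg_c	3-Phospho-D-glycerate	c	C3H4O7P
6pgc_c	6-Phospho-D-gluconate	c	C6H10O10P
6pgl_c	6-phospho-D-glucono-1,5-lactone	c	C6H9O9P
ac_c	Acetate	c	C2H3O2
ac_e	Acetate	e	C2H3O2
acald_c	Acetaldehyde	c	C2H4O
acald_e	Acetaldehyde	e	C2H4O
accoa_c	Acetyl-CoA	c	C23H34N7O17P3S
acon_C_c	cis-Aconitate	c	C6H3O6
actp_c	Acetyl phosphate	c	C2H3O5P
adp_c	ADP	c	C10H12N5O10P2
akg_c	2-Oxoglutarate	c	C5H4O5
akg_e	2-Oxoglutarate	e	C5H4O5
amp_c	AMP	c	C10H12N5O7P
atp_c	ATP	c	C10H12N5O13P3
cit_c	Citrate	c	C6H5O7
co2_c	CO2	c	CO2
co2_e	CO2	e	CO2
coa_c	Coenzyme A	c	C21H32N7O16P3S
dhap_c	Dihydroxyacetone phosphate	c	C3H5O6P
e4p_c	D-Erythrose 4-phosphate	c	C4H7O7P
etoh_c	Ethanol	c	C2H6O
etoh_e	Ethanol	e	C2H6O
f6p_c	D-Fructose 6-phosphate	c	C6H11O9P
fdp_c	D-Fructose 1,6-bisphosphate	c	C6H10O12P2
for_c	Formate	c	CH1O2
for_e	Formate	e	CH1O2
fru_e	D-Fructose	e	C6H12O6
fum_c	Fumarate	c	C4H2O4
fum_e	Fumarate	e	C4H2O4
g3p_c	Glyceraldehyde 3-phosphate	c	C3H5O6P
g6p_c	D-Glucose 6-phosphate	c	C6H11O9P
glc__D_e	D-Glucose	e	C6H12O6
gln__L_c	L-Glutamine	c	C5H10N2O3
gln__L_e	L-Glutamine	e	C5H10N2O3
glu__L_c	L-Glutamate	c	C5H8NO4
glu__L_e	L-Glutamate	e	C5H8NO4
glx_c	Glyoxylate	c	C2H1O3
h2o_c	H2O	c	H2O
h2o_e	H2O	e	H2O
h_c	H+	c	H
h_e	H+	e	H
icit_c	Isocitrate	c	C6H5O7
lac__D_c	D-Lactate	c	C3H5O3
lac__D_e	D-Lactate	e	C3H5O3
mal__L_c	L-Malate	c	C4H4O5
mal__L_e	L-Malate	e	C4H4O5
nad_c	Nicotinamide adenine dinucleotide	c	C21H26N7O14P2
nadh_c	Nicotinamide adenine dinucleotide - reduced	c	C21H27N7O14P2
nadp_c	Nicotinamide adenine dinucleotide phosphate	c	C21H25N7O17P3
nadph_c	Nicotinamide adenine dinucleotide phosphate - reduced	c	C21H26N7O17P3
nh4_c	Ammonium	c	H4N
nh4_e	Ammonium	e	H4N
o2_c	O2	c	O2
o2_e	O2	e	O2
oaa_c	Oxaloacetate	c	C4H2O5
pep_c	Phosphoenolpyruvate	c	C3H2O6P
pi_c	Phosphate	c	HO4P
pi_e	Phosphate	e	HO4P
pyr_c	Pyruvate	c	C3H3O3
pyr_e	Pyruvate	e	C3H3O3
q8_c	Ubiquinone-8	c	C49H74O4
q8h2_c	Ubiquinol-8	c	C49H76O4
r5p_c	alpha-D-Ribose 5-phosphate	c	C5H9O8P
ru5p__D_c	D-Ribulose 5-phosphate	c	C5H9O8P
s7p_c	Sedoheptulose 7-phosphate	c	C7H13O10P
succ_c	Succinate	c	C4H4O4
succ_e	Succinate	e	C4H4O4
succoa_c	Succinyl-CoA	c	C25H35N7O19P3S
xu5p__D_c	D-Xylulose 5-phosphate	c	C5H9O8P
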