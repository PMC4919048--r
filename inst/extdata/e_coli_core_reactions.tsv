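id	name	lower	upper	equation
ACALD	acetaldehyde dehydrogenase (acetylating)	-1000	1000	1 acald_c + 1 coa_c + 1 nad_c <-> 1 accoa_c + 1 h_c + 1 nadh_c
ACALDt	R acetaldehyde reversible - transport	-1000	1000	1 acald_e <-> 1 acald_c
ACKr	acetate kinase	-1000	1000	1 ac_c + 1 atp_c <-> 1 actp_c + 1 adp_c
ACONTa	aconitase (half-reaction A, Citrate hydro-lyase)	-1000	1000	1 cit_c <-> 1 acon_C_c + 1 h2o_c
ACONTb	aconitase (half-reaction B, Isocitrate hydro-lyase)	-1000	1000	1 acon_C_c + 1 h2o_c <-> 1 icit_c
ACt2r	R acetate reversible transport via proton - symport	-1000	1000	1 ac_e + 1 h_e <-> 1 ac_c + 1 h_c
ADK1	adenylate kinase	-1000	1000	1 amp_c + 1 atp_c <-> 2 adp_c
AKGDH	2-Oxogluterate dehydrogenase	0	1000	1 akg_c + 1 coa_c + 1 nad_c <-> 1 co2_c + 1 nadh_c + 1 succoa_c
AKGt2r	R 2 oxoglutarate reversible transport via - symport	-1000	1000	1 akg_e + 1 h_e <-> 1 akg_c + 1 h_c
ALCD2x	alcohol dehydrogenase (ethanol)	-1000	1000	1 etoh_c + 1 nad_c <-> 1 acald_c + 1 h_c + 1 nadh_c
ATPM	ATP maintenance requirement	8.39	1000	1 atp_c + 1 h2o_c <-> 1 adp_c + 1 h_c + 1 pi_c
ATPS4r	ATP synthase (four protons for one ATP)	-1000	1000	1 adp_c + 4 h_e + 1 pi_c <-> 1 atp_c + 1 h2o_c + 3 h_c
Biomass_Ecoli_core	Biomass Objective Function with GAM	0	1000	1.496 3pg_c + 3.7478 accoa_c + 59.81 atp_c + 0.361 e4p_c + 0.0709 f6p_c + 0.129 g3p_c + 0.205 g6p_c + 0.2557 gln__L_c + 4.9414 glu__L_c + 59.81 h2o_c + 3.547 nad_c + 13.0279 nadph_c + 1.7867 oaa_c + 0.5191 pep_c + 2.8328 pyr_c + 0.8977 r5p_c <-> 59.81 adp_c + 4.1182 akg_c + 3.7478 coa_c + 59.81 h_c + 3.547 nadh_c + 13.0279 nadp_c + 59.81 pi_c
CO2t	R CO2 transporter via - diffusion	-1000	1000	1 co2_e <-> 1 co2_c
CS	citrate synthase	0	1000	1 accoa_c + 1 h2o_c + 1 oaa_c <-> 1 cit_c + 1 coa_c + 1 h_c
CYTBD	cytochrome oxidase bd (ubiquinol-8: 2 protons)	0	1000	2 h_c + 0.5 o2_c + 1 q8h2_c <-> 1 h2o_c + 2 h_e + 1 q8_c
D_LACt2	R D lactate transport via proton - symport	-1000	1000	1 h_e + 1 lac__D_e <-> 1 h_c + 1 lac__D_c
ENO	enolase	-1000	1000	1 2pg_c <-> 1 h2o_c + 1 pep_c
ETOHt2r	ETOHt2r	-1000	1000	1 etoh_e + 1 h_e <-> 1 etoh_c + 1 h_c
EX_ac_e	Acetate exchange	0	1000	1 ac_e <-> 
EX_acald_e	Acetaldehyde exchange	0	1000	1 acald_e <-> 
EX_akg_e	2-Oxoglutarate exchange	0	1000	1 akg_e <-> 
EX_co2_e	CO2 exchange	-1000	1000	1 co2_e <-> 
EX_etoh_e	Ethanol exchange	0	1000	1 etoh_e <-> 
EX_for_e	Formate exchange	0	1000	1 for_e <-> 
EX_fru_e	D-Fructose exchange	0	1000	1 fru_e <-> 
EX_fum_e	Fumarate exchange	0	1000	1 fum_e <-> 
EX_glc__D_e	D-Glucose exchange	-10	1000	1 glc__D_e <-> 
EX_gln__L_e	L-Glutamine exchange	0	1000	1 gln__L_e <-> 
EX_glu__L_e	L-Glutamate exchange	0	1000	1 glu__L_e <-> 
EX_h2o_e	H2O exchange	-1000	1000	1 h2o_e <-> 
EX_h_e	H+ exchange	-1000	1000	1 h_e <-> 
EX_lac__D_e	D-lactate exchange	0	1000	1 lac__D_e <-> 
EX_mal__L_e	L-Malate exchange	0	1000	1 mal__L_e <-> 
EX_nh4_e	Ammonia exchange	-1000	1000	1 nh4_e <-> 
EX_o2_e	O2 exchange	-1000	1000	1 o2_e <-> 
EX_pi_e	Phosphate exchange	-1000	1000	1 pi_e <-> 
EX_pyr_e	Pyruvate exchange	0	1000	1 pyr_e <-> 
EX_succ_e	Succinate exchange	0	1000	1 succ_e <-> 
FBA	fructose-bisphosphate aldolase	-1000	1000	1 fdp_c <-> 1 dhap_c + 1 g3p_c
FBP	fructose-bisphosphatase	0	1000	1 fdp_c + 1 h2o_c <-> 1 f6p_c + 1 pi_c
FORt2	formate transport in via proton symport	0	1000	1 for_e + 1 h_e <-> 1 for_c + 1 h_c
FORti	formate transport via diffusion	0	1000	1 for_c <-> 1 for_e
FRD7	fumarate reductase	0	1000	1 fum_c + 1 q8h2_c <-> 1 q8_c + 1 succ_c
FRUpts2	R Fructose transport via PEPPyr PTS-f6p - generating	0	1000	1 fru_e + 1 pep_c <-> 1 f6p_c + 1 pyr_c
FUM	fumarase	-1000	1000	1 fum_c + 1 h2o_c <-> 1 mal__L_c
FUMt2_2	R Fumarate transport via proton symport-2 - H	0	1000	1 fum_e + 2 h_e <-> 1 fum_c + 2 h_c
G6PDH2r	glucose 6-phosphate dehydrogenase	-1000	1000	1 g6p_c + 1 nadp_c <-> 1 6pgl_c + 1 h_c + 1 nadph_c
GAPD	glyceraldehyde-3-phosphate dehydrogenase	-1000	1000	1 g3p_c + 1 nad_c + 1 pi_c <-> 1 13dpg_c + 1 h_c + 1 nadh_c
GLCpts	D-glucose transport via PEP:Pyr PTS	0	1000	1 glc__D_e + 1 pep_c <-> 1 g6p_c + 1 pyr_c
GLNS	glutamine synthetase	0	1000	1 atp_c + 1 glu__L_c + 1 nh4_c <-> 1 adp_c + 1 gln__L_c + 1 h_c + 1 pi_c
GLNabc	GLNabc	0	1000	1 atp_c + 1 gln__L_e + 1 h2o_c <-> 1 adp_c + 1 gln__L_c + 1 h_c + 1 pi_c
GLUDy	glutamate dehydrogenase (NADP)	-1000	1000	1 glu__L_c + 1 h2o_c + 1 nadp_c <-> 1 akg_c + 1 h_c + 1 nadph_c + 1 nh4_c
GLUN	glutaminase	0	1000	1 gln__L_c + 1 h2o_c <-> 1 glu__L_c + 1 nh4_c
GLUSy	glutamate synthase (NADPH)	0	1000	1 akg_c + 1 gln__L_c + 1 h_c + 1 nadph_c <-> 2 glu__L_c + 1 nadp_c
GLUt2r	R L glutamate transport via proton - symport-reversible	-1000	1000	1 glu__L_e + 1 h_e <-> 1 glu__L_c + 1 h_c
GND	phosphogluconate dehydrogenase	0	1000	1 6pgc_c + 1 nadp_c <-> 1 co2_c + 1 nadph_c + 1 ru5p__D_c
H2Ot	R H2O transport via - diffusion	-1000	1000	1 h2o_e <-> 1 h2o_c
ICDHyr	isocitrate dehydrogenase (NADP)	-1000	1000	1 icit_c + 1 nadp_c <-> 1 akg_c + 1 co2_c + 1 nadph_c
ICL	Isocitrate lyase	0	1000	1 icit_c <-> 1 glx_c + 1 succ_c
LDH_D	D-lactate dehydrogenase	-1000	1000	1 lac__D_c + 1 nad_c <-> 1 h_c + 1 nadh_c + 1 pyr_c
MALS	malate synthase	0	1000	1 accoa_c + 1 glx_c + 1 h2o_c <-> 1 coa_c + 1 h_c + 1 mal__L_c
MALt2_2	R Malate transport via proton symport-2 - H	0	1000	2 h_e + 1 mal__L_e <-> 2 h_c + 1 mal__L_c
MDH	malate dehydrogenase	-1000	1000	1 mal__L_c + 1 nad_c <-> 1 h_c + 1 nadh_c + 1 oaa_c
ME1	malic enzyme (NAD)	0	1000	1 mal__L_c + 1 nad_c <-> 1 co2_c + 1 nadh_c + 1 pyr_c
ME2	malic enzyme (NADP)	0	1000	1 mal__L_c + 1 nadp_c <-> 1 co2_c + 1 nadph_c + 1 pyr_c
NADH16	NADH dehydrogenase (ubiquinone-8 & 3 protons)	0	1000	4 h_c + 1 nadh_c + 1 q8_c <-> 3 h_e + 1 nad_c + 1 q8h2_c
NADTRHD	NAD transhydrogenase	0	1000	1 nad_c + 1 nadph_c <-> 1 nadh_c + 1 nadp_c
NH4t	R ammonia reversible - transport	-1000	1000	1 nh4_e <-> 1 nh4_c
O2t	R o2 - transport-diffusion	-1000	1000	1 o2_e <-> 1 o2_c
PDH	pyruvate dehydrogenase	0	1000	1 coa_c + 1 nad_c + 1 pyr_c <-> 1 accoa_c + 1 co2_c + 1 nadh_c
PFK	phosphofructokinase	0	1000	1 atp_c + 1 f6p_c <-> 1 adp_c + 1 fdp_c + 1 h_c
PFL	pyruvate formate lyase	0	1000	1 coa_c + 1 pyr_c <-> 1 accoa_c + 1 for_c
PGI	glucose-6-phosphate isomerase	-1000	1000	1 g6p_c <-> 1 f6p_c
PGK	phosphoglycerate kinase	-1000	1000	1 3pg_c + 1 atp_c <-> 1 13dpg_c + 1 adp_c
PGL	6-phosphogluconolactonase	0	1000	1 6pgl_c + 1 h2o_c <-> 1 6pgc_c + 1 h_c
PGM	phosphoglycerate mutase	-1000	1000	1 2pg_c <-> 1 3pg_c
PIt2r	R phosphate reversible transport via - symport	-1000	1000	1 h_e + 1 pi_e <-> 1 h_c + 1 pi_c
PPC	phosphoenolpyruvate carboxylase	0	1000	1 co2_c + 1 h2o_c + 1 pep_c <-> 1 h_c + 1 oaa_c + 1 pi_c
PPCK	phosphoenolpyruvate carboxykinase	0	1000	1 atp_c + 1 oaa_c <-> 1 adp_c + 1 co2_c + 1 pep_c
PPS	phosphoenolpyruvate synthase	0	1000	1 atp_c + 1 h2o_c + 1 pyr_c <-> 1 amp_c + 2 h_c + 1 pep_c + 1 pi_c
PTAr	phosphotransacetylase	-1000	1000	1 accoa_c + 1 pi_c <-> 1 actp_c + 1 coa_c
PYK	pyruvate kinase	0	1000	1 adp_c + 1 h_c + 1 pep_c <-> 1 atp_c + 1 pyr_c
PYRt2	R pyruvate transport in via proton - symport	-1000	1000	1 h_e + 1 pyr_e <-> 1 h_c + 1 pyr_c
RPE	ribulose 5-phosphate 3-epimerase	-1000	1000	1 ru5p__D_c <-> 1 xu5p__D_c
RPI	ribose-5-phosphate isomerase	-1000	1000	1 r5p_c <-> 1 ru5p__D_c
SUCCt2_2	R succinate transport via proton symport-2 - H	0	1000	2 h_e + 1 succ_e <-> 2 h_c + 1 succ_c
SUCCt3	succinate transport out via proton antiport	0	1000	1 h_e + 1 succ_c <-> 1 h_c + 1 succ_e
SUCDi	succinate dehydrogenase (irreversible)	0	1000	1 q8_c + 1 succ_c <-> 1 fum_c + 1 q8h2_c
SUCOAS	succinyl-CoA synthetase (ADP-forming)	-1000	1000	1 atp_c + 1 coa_c + 1 succ_c <-> 1 adp_c + 1 pi_c + 1 succoa_c
TALA	transaldolase	-1000	1000	1 g3p_c + 1 s7p_c <-> 1 e4p_c + 1 f6p_c
THD2	R NAD - P-transhydrogenase	0	1000	2 h_e + 1 nadh_c + 1 nadp_c <-> 2 h_c + 1 nad_c + 1 nadph_c
TKT1	transketolase	-1000	1000	1 r5p_c + 1 xu5p__D_c <-> 1 g3p_c + 1 s7p_c
TKT2	transketolase	-1000	1000	1 e4p_c + 1 xu5p__D_c <-> 1 f6p_c + 1 g3p_c
TPI	triose-phosphate isomerase	-1000	1000	1 dhap_c <-> 1 g3p_c
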