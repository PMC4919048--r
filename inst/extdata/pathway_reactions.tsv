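id	enzyme	pathways	noncycle_in	action	atp_equivalents	lower	upper	equation
PPR	proton-pumping rhodopsin	energy	energy	add	0	0	0	1 h_c -> 1 h_e
EX_ee	extracellular electron exchange	energy	energy	add	0	-1000	1000	1 e_e ->
FDR	ferredoxin reduction (electron uptake)	energy	energy	add	0	0	1000	1 e_e + 1 fdxox_c -> 1 fdxrd_c
NADPHR	NADPH regeneration (electron uptake)	energy	energy	add	0	0	1000	2 e_e + 1 h_c + 1 nadp_c -> 1 nadph_c
TPI	triose-phosphate isomerase	calvin		reuse	0	-1000	1000	1 dhap_c <-> 1 g3p_c
FBA	fructose-bisphosphate aldolase	calvin		reuse	0	-1000	1000	1 fdp_c <-> 1 dhap_c + 1 g3p_c
FBP	fructose-bisphosphatase	calvin		reuse	0	0	1000	1 fdp_c + 1 h2o_c -> 1 f6p_c + 1 pi_c
TKT1	transketolase	calvin		reuse	0	-1000	1000	1 r5p_c + 1 xu5p__D_c <-> 1 g3p_c + 1 s7p_c
TKT2	transketolase	calvin		reuse	0	-1000	1000	1 e4p_c + 1 xu5p__D_c <-> 1 f6p_c + 1 g3p_c
SBA	sedoheptulose/fructose-bisphosphate aldolase	calvin		add	0	-1000	1000	1 dhap_c + 1 e4p_c <-> 1 s17bp_c
SBP	sedoheptulose-bisphosphatase	calvin		add	0	0	1000	1 h2o_c + 1 s17bp_c -> 1 pi_c + 1 s7p_c
RPI	ribose-5-phosphate isomerase	calvin		reuse	0	-1000	1000	1 r5p_c <-> 1 ru5p__D_c
RPE	ribulose-phosphate 3-epimerase	calvin		reuse	0	-1000	1000	1 ru5p__D_c <-> 1 xu5p__D_c
PRUK	phosphoribulokinase	calvin		add	0	0	1000	1 atp_c + 1 ru5p__D_c -> 1 adp_c + 1 h_c + 1 rb15bp_c
RBPC	ribulose-bisphosphate carboxylase	calvin		add	0	0	1000	1 co2_c + 1 h2o_c + 1 rb15bp_c -> 2 3pg_c + 2 h_c
PGK	phosphoglycerate kinase	calvin		reuse	0	-1000	1000	1 3pg_c + 1 atp_c <-> 1 13dpg_c + 1 adp_c
GAPD	glyceraldehyde-3-phosphate dehydrogenase	calvin		reuse	0	-1000	1000	1 g3p_c + 1 nad_c + 1 pi_c <-> 1 13dpg_c + 1 h_c + 1 nadh_c
MDH	malate dehydrogenase	rtca;dc4hb;pyrs_pyrc_glx;pyrs_pepc_glx		reuse	0	-1000	1000	1 mal__L_c + 1 nad_c <-> 1 h_c + 1 nadh_c + 1 oaa_c
FUM	fumarate hydratase	rtca;dc4hb;pyrs_pyrc_glx;pyrs_pepc_glx		reuse	0	-1000	1000	1 fum_c + 1 h2o_c <-> 1 mal__L_c
FRD7	fumarate reductase	rtca;dc4hb;pyrs_pyrc_glx;pyrs_pepc_glx		reuse	0	0	1000	1 fum_c + 1 q8h2_c -> 1 q8_c + 1 succ_c
SUCOAS	succinyl-CoA synthetase	rtca;dc4hb		reuse	0	-1000	1000	1 atp_c + 1 coa_c + 1 succ_c <-> 1 adp_c + 1 pi_c + 1 succoa_c
OGOR	2-oxoglutarate synthase	rtca		add	0	0	1000	1 co2_c + 1 h_c + 1 succoa_c + 2 fdxrd_c -> 1 akg_c + 1 coa_c + 2 fdxox_c
ICDHyr	isocitrate dehydrogenase	rtca		reuse	0	-1000	1000	1 icit_c + 1 nadp_c <-> 1 akg_c + 1 co2_c + 1 nadph_c
ACONTa	aconitate hydratase	rtca;pyrs_pyrc_glx;pyrs_pepc_glx		reuse	0	-1000	1000	1 cit_c <-> 1 acon_C_c + 1 h2o_c
ACONTb	aconitate hydratase	rtca;pyrs_pyrc_glx;pyrs_pepc_glx		reuse	0	-1000	1000	1 acon_C_c + 1 h2o_c <-> 1 icit_c
ACL	ATP citrate lyase	rtca;pyrs_pyrc_glx;pyrs_pepc_glx		add	0	0	1000	1 atp_c + 1 cit_c + 1 coa_c -> 1 accoa_c + 1 adp_c + 1 oaa_c + 1 pi_c
PYRS	pyruvate synthase	rtca;hp4hb;dc4hb;pyrs_pyrc_glx;pyrs_pepc_glx	rtca;hp4hb	add	0	0	1000	1 accoa_c + 1 co2_c + 1 h_c + 2 fdxrd_c -> 1 coa_c + 2 fdxox_c + 1 pyr_c
ACCOAC	acetyl-CoA carboxylase	hp4hb		add	0	0	1000	1 accoa_c + 1 atp_c + 1 hco3_c -> 1 adp_c + 1 h_c + 1 malcoa_c + 1 pi_c
MCR	malonyl-CoA reductase (bifunctional)	hp4hb		add	0	0	1000	2 h_c + 1 malcoa_c + 2 nadph_c -> 1 coa_c + 1 hpp_c + 2 nadp_c
PCS	propionyl-CoA synthase (trifunctional)	hp4hb		add	2	0	1000	1 atp_c + 1 coa_c + 1 hpp_c + 1 nadph_c -> 1 amp_c + 1 h2o_c + 1 nadp_c + 1 ppcoa_c + 1 ppi_c
PPCOAC	propionyl-CoA carboxylase	hp4hb		add	0	0	1000	1 atp_c + 1 hco3_c + 1 ppcoa_c -> 1 adp_c + 1 h_c + 1 mmcoa_c + 1 pi_c
MMCE	methylmalonyl-CoA epimerase	hp4hb		add	0	0	1000	1 mmcoa_c -> 1 mmcoar_c
MMM	methylmalonyl-CoA mutase	hp4hb		add	0	0	1000	1 mmcoar_c -> 1 succoa_c
SUCOAR	succinyl-CoA reductase	hp4hb;dc4hb		add	0	0	1000	1 h_c + 1 nadph_c + 1 succoa_c -> 1 coa_c + 1 nadp_c + 1 sucsal_c
SSALR	succinate-semialdehyde reductase	hp4hb;dc4hb		add	0	0	1000	1 h_c + 1 nadph_c + 1 sucsal_c -> 1 ghb_c + 1 nadp_c
HBCOAS	4-hydroxybutyryl-CoA synthetase	hp4hb;dc4hb		add	2	0	1000	1 atp_c + 1 coa_c + 1 ghb_c -> 1 4hbcoa_c + 1 amp_c + 1 ppi_c
HBCOADH	4-hydroxybutyryl-CoA dehydratase	hp4hb;dc4hb		add	0	0	1000	1 4hbcoa_c -> 1 b2coa_c + 1 h2o_c
ECOAH1r	3-hydroxyacyl-CoA dehydratase	hp4hb;dc4hb		add	0	0	1000	1 b2coa_c + 1 h2o_c -> 1 3hbcoa_c
HACD1r	3-hydroxyacyl-CoA dehydrogenase	hp4hb;dc4hb		add	0	0	1000	1 3hbcoa_c + 1 nad_c -> 1 aacoa_c + 1 h_c + 1 nadh_c
ACACT1r	acetyl-CoA C-acetyltransferase	hp4hb;dc4hb		add	0	0	1000	1 aacoa_c + 1 coa_c -> 2 accoa_c
PPS	pyruvate water dikinase	dc4hb;pyrs_pepc_glx		reuse	2	0	1000	1 atp_c + 1 h2o_c + 1 pyr_c -> 1 amp_c + 2 h_c + 1 pep_c + 1 pi_c
PPC	phosphoenolpyruvate carboxylase	dc4hb;pyrs_pepc_glx		reuse	0	0	1000	1 co2_c + 1 h2o_c + 1 pep_c -> 1 h_c + 1 oaa_c + 1 pi_c
PC	pyruvate carboxylase	pyrs_pyrc_glx		add	0	0	1000	1 atp_c + 1 hco3_c + 1 pyr_c -> 1 adp_c + 1 h_c + 1 oaa_c + 1 pi_c
MTK	malate thiokinase	pyrs_pyrc_glx;pyrs_pepc_glx		add	0	0	1000	1 atp_c + 1 coa_c + 1 mal__L_c -> 1 adp_c + 1 mlycoa_c + 1 pi_c
MCL	malyl-CoA lyase	pyrs_pyrc_glx;pyrs_pepc_glx		add	0	0	1000	1 mlycoa_c -> 1 accoa_c + 1 glx_c
ICL	isocitrate lyase	pyrs_pyrc_glx;pyrs_pepc_glx		widen	0	-1000	1000	1 icit_c <-> 1 glx_c + 1 succ_c
HCO3E	carbonic anhydrase	hp4hb;pyrs_pyrc_glx	hp4hb;pyrs_pyrc_glx	add	0	-1000	1000	1 co2_c + 1 h2o_c <-> 1 h_c + 1 hco3_c
PPA	inorganic pyrophosphatase	hp4hb;dc4hb	hp4hb;dc4hb	add	0	0	1000	1 h2o_c + 1 ppi_c -> 1 h_c + 2 pi_c
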