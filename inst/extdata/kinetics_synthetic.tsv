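# Synthetic reconstruction of enzyme specific activities (umol substrate/mg
# protein/min, saturating substrates including CO2/HCO3-) and stoichiometric
# coefficients w per mole of pyruvate end product. Values for the
# ferredoxin-oxidoreductases come from the trimmed aggregation of the
# observation collections in activity_observations_synthetic.tsv.
pathway	reaction_id	enzyme	w	specific_activity
calvin	RBPC	ribulose-bisphosphate carboxylase	3	3.5
calvin	PGK	phosphoglycerate kinase	6	450
calvin	GAPD	glyceraldehyde-3-phosphate dehydrogenase	6	150
calvin	TPI	triose-phosphate isomerase	2	5000
calvin	FBA	fructose-bisphosphate aldolase	1	25
calvin	FBP	fructose-bisphosphatase	1	24
calvin	TKT2	transketolase	1	60
calvin	SBA	sedoheptulose/fructose-bisphosphate aldolase	1	7
calvin	SBP	sedoheptulose-bisphosphatase	1	15
calvin	TKT1	transketolase	1	60
calvin	RPI	ribose-5-phosphate isomerase	1	600
calvin	RPE	ribulose-phosphate 3-epimerase	2	1000
calvin	PRUK	phosphoribulokinase	3	200
rtca	MDH	malate dehydrogenase	1	900
rtca	FUM	fumarate hydratase	1	450
rtca	FRD7	fumarate reductase	1	60
rtca	SUCOAS	succinyl-CoA synthetase	1	55
rtca	OGOR	2-oxoglutarate synthase	1	5
rtca	ICDHyr	isocitrate dehydrogenase	1	80
rtca	ACONT	aconitate hydratase	1	30
rtca	ACL	ATP citrate lyase	1	8
rtca	PYRS	pyruvate synthase	1	10
hp4hb	ACCOAC	acetyl-CoA carboxylase	1	6
hp4hb	MCR	malonyl-CoA reductase (bifunctional)	1	2.8
hp4hb	PCS	propionyl-CoA synthase (trifunctional)	1	1.8
hp4hb	PPCOAC	propionyl-CoA carboxylase	1	9
hp4hb	MMCE	methylmalonyl-CoA epimerase	1	300
hp4hb	MMM	methylmalonyl-CoA mutase	1	30
hp4hb	SUCOAR	succinyl-CoA reductase	1	4
hp4hb	SSALR	succinate-semialdehyde reductase	1	70
hp4hb	HBCOAS	4-hydroxybutyryl-CoA synthetase	1	20
hp4hb	HBCOADH	4-hydroxybutyryl-CoA dehydratase	1	3.5
hp4hb	ECOAH1r	3-hydroxyacyl-CoA dehydratase	1	600
hp4hb	HACD1r	3-hydroxyacyl-CoA dehydrogenase	1	400
hp4hb	ACACT1r	acetyl-CoA C-acetyltransferase	1	500
hp4hb	PYRS	pyruvate synthase	1	10
dc4hb	PYRS	pyruvate synthase	2	10
dc4hb	PPS	pyruvate water dikinase	1	25
dc4hb	PPC	phosphoenolpyruvate carboxylase	1	150
dc4hb	MDH	malate dehydrogenase	1	900
dc4hb	FUM	fumarate hydratase	1	450
dc4hb	FRD7	fumarate reductase	1	60
dc4hb	SUCOAS	succinyl-CoA synthetase	1	55
dc4hb	SUCOAR	succinyl-CoA reductase	1	4
dc4hb	SSALR	succinate-semialdehyde reductase	1	70
dc4hb	HBCOAS	4-hydroxybutyryl-CoA synthetase	1	20
dc4hb	HBCOADH	4-hydroxybutyryl-CoA dehydratase	1	3.5
dc4hb	ECOAH1r	3-hydroxyacyl-CoA dehydratase	1	600
dc4hb	HACD1r	3-hydroxyacyl-CoA dehydrogenase	1	400
dc4hb	ACACT1r	acetyl-CoA C-acetyltransferase	1	500
pyrs_pyrc_glx	PYRS	pyruvate synthase	2	10
pyrs_pyrc_glx	PC	pyruvate carboxylase	1	12
pyrs_pyrc_glx	MDH	malate dehydrogenase	2	900
pyrs_pyrc_glx	MTK	malate thiokinase	1	8
pyrs_pyrc_glx	MCL	malyl-CoA lyase	1	8
pyrs_pyrc_glx	ICL	isocitrate lyase	1	20
pyrs_pyrc_glx	ACONT	aconitate hydratase	1	30
pyrs_pyrc_glx	ACL	ATP citrate lyase	1	8
pyrs_pyrc_glx	FUM	fumarate hydratase	1	450
pyrs_pyrc_glx	FRD7	fumarate reductase	1	60
pyrs_pepc_glx	PYRS	pyruvate synthase	2	10
pyrs_pepc_glx	PPS	pyruvate water dikinase	1	7
pyrs_pepc_glx	PPC	phosphoenolpyruvate carboxylase	1	150
pyrs_pepc_glx	MDH	malate dehydrogenase	2	900
pyrs_pepc_glx	MTK	malate thiokinase	1	8
pyrs_pepc_glx	MCL	malyl-CoA lyase	1	8
pyrs_pepc_glx	ICL	isocitrate lyase	1	20
pyrs_pepc_glx	ACONT	aconitate hydratase	1	30
pyrs_pepc_glx	ACL	ATP citrate lyase	1	8
pyrs_pepc_glx	FUM	fumarate hydratase	1	450
pyrs_pepc_glx	FRD7	fumarate reductase	1	60
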