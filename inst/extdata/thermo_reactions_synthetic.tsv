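# Synthetic reconstruction of standard transformed reaction Gibbs energies
# (pH 7.5, ionic strength 0.2 M, 298.15 K) for the carbon fixation pathway
# reactions, written at cofactor level so that cofactor ratios enter the MDF
# only through concentration constraints. Values are anchored on standard
# biochemical reference energies (phosphoanhydride and thioester hydrolysis,
# two-electron redox potentials, textbook glycolytic/Calvin-cycle energies);
# se holds a Component-Contribution-style standard error of the estimate.
# dnh is the net transformed proton production used for first-order pH
# adjustment: drG0'(pH) = drG0'(7.5) + dnh * RT * ln(10) * (pH - 7.5).
pathway	reaction_id	enzyme	equation	drg0_prime	se	dnh
calvin	RBPC	ribulose-bisphosphate carboxylase	1 rb15bp + 1 co2 -> 2 3pg	-35.0	6.0	1
calvin	PGK	phosphoglycerate kinase	1 3pg + 1 atp -> 1 13dpg + 1 adp	18.8	1.0	0
calvin	GAPD	glyceraldehyde-3-phosphate dehydrogenase	1 13dpg + 1 nadh -> 1 g3p + 1 nad + 1 pi	-2.0	1.5	0
calvin	TPI	triose-phosphate isomerase	1 g3p -> 1 dhap	-7.6	1.0	0
calvin	FBA	fructose-bisphosphate aldolase	1 dhap + 1 g3p -> 1 fdp	-23.8	2.0	0
calvin	FBP	fructose-bisphosphatase	1 fdp -> 1 f6p + 1 pi	-16.3	2.0	-1
calvin	TKT2	transketolase	1 f6p + 1 g3p -> 1 e4p + 1 xu5p	1.5	2.5	0
calvin	SBA	sedoheptulose/fructose-bisphosphate aldolase	1 e4p + 1 dhap -> 1 s17bp	-23.8	3.0	0
calvin	SBP	sedoheptulose-bisphosphatase	1 s17bp -> 1 s7p + 1 pi	-16.3	3.0	-1
calvin	TKT1	transketolase	1 s7p + 1 g3p -> 1 r5p + 1 xu5p	3.8	2.5	0
calvin	RPI	ribose-5-phosphate isomerase	1 r5p -> 1 ru5p	2.1	1.5	0
calvin	RPE	ribulose-phosphate 3-epimerase	1 xu5p -> 1 ru5p	3.4	1.5	0
calvin	PRUK	phosphoribulokinase	1 ru5p + 1 atp -> 1 rb15bp + 1 adp	-14.0	3.0	0
rtca	MDH	malate dehydrogenase	1 oaa + 1 nadh -> 1 mal + 1 nad	-28.6	1.0	0
rtca	FUM	fumarate hydratase	1 mal -> 1 fum	3.4	1.0	0
rtca	FRD7	fumarate reductase	1 fum + 1 nadh -> 1 succ + 1 nad	-68.1	4.0	0
rtca	SUCOAS	succinyl-CoA synthetase	1 succ + 1 coa + 1 atp -> 1 succoa + 1 adp + 1 pi	2.0	2.0	0
rtca	OGOR	2-oxoglutarate synthase	1 succoa + 1 co2 + 2 fdrd -> 1 akg + 1 coa + 2 fdox	13.7	9.0	1
rtca	ICDHyr	isocitrate dehydrogenase	1 akg + 1 co2 + 1 nadph -> 1 icit + 1 nadp	5.0	7.0	1
rtca	ACONT	aconitate hydratase	1 icit -> 1 cit	-6.7	1.0	0
rtca	ACL	ATP citrate lyase	1 cit + 1 atp + 1 coa -> 1 accoa + 1 oaa + 1 adp + 1 pi	6.0	4.0	0
rtca	PYRS	pyruvate synthase	1 accoa + 1 co2 + 2 fdrd -> 1 pyr + 1 coa + 2 fdox	15.1	7.5	1
hp4hb	ACCOAC	acetyl-CoA carboxylase	1 accoa + 1 hco3 + 1 atp -> 1 malcoa + 1 adp + 1 pi	-8.0	3.0	0
hp4hb	MCR	malonyl-CoA reductase (bifunctional)	1 malcoa + 2 nadph -> 1 hpp + 2 nadp + 1 coa	-14.0	5.0	0
hp4hb	PCS	propionyl-CoA synthase (trifunctional)	1 hpp + 1 coa + 1 atp + 1 nadph -> 1 ppcoa + 1 amp + 1 ppi + 1 nadp	-55.0	6.0	0
hp4hb	PPCOAC	propionyl-CoA carboxylase	1 ppcoa + 1 hco3 + 1 atp -> 1 mmcoa + 1 adp + 1 pi	-8.0	3.0	0
hp4hb	MMCE	methylmalonyl-CoA epimerase	1 mmcoa -> 1 mmcoar	0.0	1.0	0
hp4hb	MMM	methylmalonyl-CoA mutase	1 mmcoar -> 1 succoa	-6.0	2.0	0
hp4hb	SUCOAR	succinyl-CoA reductase	1 succoa + 1 nadph -> 1 sucsal + 1 coa + 1 nadp	18.1	5.5	0
hp4hb	SSALR	succinate-semialdehyde reductase	1 sucsal + 1 nadph -> 1 ghb + 1 nadp	-23.2	3.0	0
hp4hb	HBCOAS	4-hydroxybutyryl-CoA synthetase	1 ghb + 1 atp + 1 coa -> 1 hbcoa + 1 amp + 1 ppi	-5.0	4.0	0
hp4hb	HBCOADH	4-hydroxybutyryl-CoA dehydratase	1 hbcoa -> 1 b2coa	1.0	5.0	0
hp4hb	ECOAH1r	3-hydroxyacyl-CoA dehydratase	1 b2coa -> 1 hb3coa	-3.2	2.0	0
hp4hb	HACD1r	3-hydroxyacyl-CoA dehydrogenase	1 hb3coa + 1 nad -> 1 aacoa + 1 nadh	14.3	5.0	0
hp4hb	ACACT1r	acetyl-CoA C-acetyltransferase	1 aacoa + 1 coa -> 2 accoa	-26.1	2.0	0
hp4hb	PYRS	pyruvate synthase	1 accoa + 1 co2 + 2 fdrd -> 1 pyr + 1 coa + 2 fdox	15.1	7.5	1
dc4hb	PYRS	pyruvate synthase	1 accoa + 1 co2 + 2 fdrd -> 1 pyr + 1 coa + 2 fdox	15.1	7.5	1
dc4hb	PPS	pyruvate water dikinase	1 pyr + 1 atp -> 1 pep + 1 amp + 1 pi	3.9	3.0	-1
dc4hb	PPC	phosphoenolpyruvate carboxylase	1 pep + 1 co2 -> 1 oaa + 1 pi	-30.0	2.0	1
dc4hb	MDH	malate dehydrogenase	1 oaa + 1 nadh -> 1 mal + 1 nad	-28.6	1.0	0
dc4hb	FUM	fumarate hydratase	1 mal -> 1 fum	3.4	1.0	0
dc4hb	FRD7	fumarate reductase	1 fum + 1 nadh -> 1 succ + 1 nad	-68.1	4.0	0
dc4hb	SUCOAS	succinyl-CoA synthetase	1 succ + 1 coa + 1 atp -> 1 succoa + 1 adp + 1 pi	2.0	2.0	0
dc4hb	SUCOAR	succinyl-CoA reductase	1 succoa + 1 nadph -> 1 sucsal + 1 coa + 1 nadp	18.1	5.5	0
dc4hb	SSALR	succinate-semialdehyde reductase	1 sucsal + 1 nadph -> 1 ghb + 1 nadp	-23.2	3.0	0
dc4hb	HBCOAS	4-hydroxybutyryl-CoA synthetase	1 ghb + 1 atp + 1 coa -> 1 hbcoa + 1 amp + 1 ppi	-5.0	4.0	0
dc4hb	HBCOADH	4-hydroxybutyryl-CoA dehydratase	1 hbcoa -> 1 b2coa	1.0	5.0	0
dc4hb	ECOAH1r	3-hydroxyacyl-CoA dehydratase	1 b2coa -> 1 hb3coa	-3.2	2.0	0
dc4hb	HACD1r	3-hydroxyacyl-CoA dehydrogenase	1 hb3coa + 1 nad -> 1 aacoa + 1 nadh	14.3	5.0	0
dc4hb	ACACT1r	acetyl-CoA C-acetyltransferase	1 aacoa + 1 coa -> 2 accoa	-26.1	2.0	0
pyrs_pyrc_glx	PYRS	pyruvate synthase	1 accoa + 1 co2 + 2 fdrd -> 1 pyr + 1 coa + 2 fdox	15.1	7.5	1
pyrs_pyrc_glx	PC	pyruvate carboxylase	1 pyr + 1 hco3 + 1 atp -> 1 oaa + 1 adp + 1 pi	-4.0	3.0	0
pyrs_pyrc_glx	MDH	malate dehydrogenase	1 oaa + 1 nadh -> 1 mal + 1 nad	-28.6	1.0	0
pyrs_pyrc_glx	MTK	malate thiokinase	1 mal + 1 atp + 1 coa -> 1 mlycoa + 1 adp + 1 pi	12.0	3.0	0
pyrs_pyrc_glx	MCL	malyl-CoA lyase	1 mlycoa -> 1 accoa + 1 glx	9.0	3.5	0
pyrs_pyrc_glx	ICL	isocitrate lyase	1 glx + 1 succ -> 1 icit	-2.0	3.0	0
pyrs_pyrc_glx	ACONT	aconitate hydratase	1 icit -> 1 cit	-6.7	1.0	0
pyrs_pyrc_glx	ACL	ATP citrate lyase	1 cit + 1 atp + 1 coa -> 1 accoa + 1 oaa + 1 adp + 1 pi	6.0	4.0	0
pyrs_pyrc_glx	FUM	fumarate hydratase	1 mal -> 1 fum	3.4	1.0	0
pyrs_pyrc_glx	FRD7	fumarate reductase	1 fum + 1 nadh -> 1 succ + 1 nad	-68.1	4.0	0
pyrs_pepc_glx	PYRS	pyruvate synthase	1 accoa + 1 co2 + 2 fdrd -> 1 pyr + 1 coa + 2 fdox	15.1	7.5	1
pyrs_pepc_glx	PPS	pyruvate water dikinase	1 pyr + 1 atp -> 1 pep + 1 amp + 1 pi	3.9	3.0	-1
pyrs_pepc_glx	PPC	phosphoenolpyruvate carboxylase	1 pep + 1 co2 -> 1 oaa + 1 pi	-30.0	2.0	1
pyrs_pepc_glx	MDH	malate dehydrogenase	1 oaa + 1 nadh -> 1 mal + 1 nad	-28.6	1.0	0
pyrs_pepc_glx	MTK	malate thiokinase	1 mal + 1 atp + 1 coa -> 1 mlycoa + 1 adp + 1 pi	12.0	3.0	0
pyrs_pepc_glx	MCL	malyl-CoA lyase	1 mlycoa -> 1 accoa + 1 glx	9.0	3.5	0
pyrs_pepc_glx	ICL	isocitrate lyase	1 glx + 1 succ -> 1 icit	-2.0	3.0	0
pyrs_pepc_glx	ACONT	aconitate hydratase	1 icit -> 1 cit	-6.7	1.0	0
pyrs_pepc_glx	ACL	ATP citrate lyase	1 cit + 1 atp + 1 coa -> 1 accoa + 1 oaa + 1 adp + 1 pi	6.0	4.0	0
pyrs_pepc_glx	FUM	fumarate hydratase	1 mal -> 1 fum	3.4	1.0	0
pyrs_pepc_glx	FRD7	fumarate reductase	1 fum + 1 nadh -> 1 succ + 1 nad	-68.1	4.0	0
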