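# Synthetic BRENDA-style specific-activity observation collections
# (umol/mg protein/min) for enzymes whose single-value literature estimates
# were not available; the working specific activity is the mean after
# discarding the lower 50% and upper 10% of the sorted observations.
reaction_id	enzyme	values
PYRS	pyruvate synthase	0.5;1;2;3;5;8;9;11;12;40
OGOR	2-oxoglutarate synthase	0.3;0.8;1;2;2.5;4;4.5;5.5;6;30
MCR	malonyl-CoA reductase (bifunctional)	0.4;1.1;2.2;2.8;3.4
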