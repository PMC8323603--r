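# contigDamage logistic accuracy model
intercept	-13.246416016655255
predictor	damage	21.439267913613122	identity
predictor	coverage	3.0847734732085961	log10p1
predictor	contig_length	2.6477691475552634	log10
provenance	simulator grid: damage 0-0.2 (6 levels) x coverage 1-150 (6) x length 1-30 kb (4) x GC 0.31/0.47/0.72, seed 20210, 432 labelled contigs, 10 balanced down-sampling repeats, mean coefficients
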