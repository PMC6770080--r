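SNP	Chromosome	EffectAllele	OtherAllele	Beta	SE	Pvalue	EAF	N
rs11057830	12	A	G	0.03	0.01	8.2e-9	0.15	7781
rs2108622	19	T	C	0.03	0.01	1.4e-10	0.21	7781
rs964184	11	G	C	0.04	0.01	7.8e-12	0.15	7781
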