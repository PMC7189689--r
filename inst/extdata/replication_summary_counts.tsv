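class	lsadt_hyper	lsadt_hypo	madt_hyper	madt_hypo	replicated	validated	universe
both	149	10	325	90	55	3	10096
male_only	434	103	466	886	123	16	10096
female_only	897	462	887	239	293	24	10096
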