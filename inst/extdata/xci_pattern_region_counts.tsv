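gene_region	A	B	C	D	REST
1stExon	471	43	146	7	123
3'UTR	19	3	281	14	82
5'UTR	711	102	225	38	313
Body	669	90	891	33	420
Intergenic	433	114	546	23	388
TSS1500	854	122	600	24	462
TSS200	1130	174	255	10	280
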