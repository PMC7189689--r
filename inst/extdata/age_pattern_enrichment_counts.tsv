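cohort	sex	significance	A	B	C	D	REST
LSADT	female	insignificant	3890	463	2269	122	1834
LSADT	female	significant	397	185	675	27	234
MADT	female	insignificant	4128	455	1960	137	1875
MADT	female	significant	159	193	984	12	193
LSADT	male	insignificant	4195	632	2505	140	1928
LSADT	male	significant	92	16	439	9	140
MADT	male	insignificant	3664	536	2305	126	1698
MADT	male	significant	623	112	639	23	370
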