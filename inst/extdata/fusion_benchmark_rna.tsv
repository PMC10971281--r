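gene_a	gene_b	bnd_a	bnd_b	reads
TMEM217	KMT5B	chr6:37243578	chr11:68174277	64
BCR	ABL1	chr22:23219813	chr9:130854197	210
NR3C1	DNM2	chr5:143350483	chr19:10739595	48
HLF	TCF3	chr17:55319005	chr19:1619186	73
ABL1	ZMIZ1	chr9:130746466	chr10:79299129	94
NKD2	ZCCHC16	chr5_KI270792v1alt:30755	chrX:112294171	3
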