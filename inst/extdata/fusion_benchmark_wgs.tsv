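gene_a	gene_b	chrom_a	pos_a	chrom_b	pos_b	sv_id	svtype	sample	technology	orientation_compatible	flags
TMEM217	KMT5B	chr6	37243578	chr11	68174277	W001	TRA	ALL-19	WGS	TRUE	
BCR	ABL1	chr22	23219813	chr9	130854197	W002	TRA	G2650	WGS	TRUE	
NR3C1	DNM2	chr5	143350483	chr19	10739595	W003	TRA	G2650	WGS	TRUE	
BCR	ABL1	chr22	23290277	chr9	130846798	W004	TRA	ICN1	WGS	TRUE	
BCR	ABL1	chr22	23290361	chr9	130821448	W005	TRA	MXP3	WGS	TRUE	
ABL1	ZMIZ1	chr9	130746469	chr10	79299033	W006	TRA	PAVCYL	WGS	TRUE	
HLF	TCF3	chr17	55319005	chr19	1619186	W007	TRA	ALL-07	WGS	TRUE	
ABL1	ZMIZ1	chr9	130746466	chr10	79299129	W008	TRA	PAWFUU	WGS	TRUE	
NKD2	ZCCHC16	chr5_KI270792v1alt	30755	chrX	112294171	W009	TRA	ICN1	WGS	TRUE	
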