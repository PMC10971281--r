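gene_a	gene_b	chrom_a	pos_a	chrom_b	pos_b	sv_id	svtype	sample	technology	orientation_compatible	flags
TMEM217	KMT5B	chr6	37241200	chr11	68171900	B001	TRA	ALL-19	OGM	TRUE	
BCR	ABL1	chr22	23217500	chr9	130851800	B002	TRA	G2650	OGM	TRUE	
NR3C1	DNM2	chr5	143348100	chr19	10737200	B003	TRA	G2650	OGM	TRUE	
BCR	ABL1	chr22	23288000	chr9	130844400	B004	TRA	ICN1	OGM	TRUE	
BCR	ABL1	chr22	23287900	chr9	130819100	B005	TRA	MXP3	OGM	TRUE	
ABL1	ZMIZ1	chr9	130744100	chr10	79296800	B006	TRA	PAVCYL	OGM	TRUE	
HLF	TCF3	chr17	55316700	chr19	1616900	B007	TRA	ALL-07	OGM	TRUE	
ABL1	ZMIZ1	chr9	130744100	chr10	79296900	B008	TRA	PAWFUU	OGM	TRUE	
NKD2	ZCCHC16	chr5_KI270792v1alt	28400	chrX	112291800	B009	TRA	ICN1	OGM	TRUE	
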