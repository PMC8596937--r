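# curated TNBC blood immunomethylomics marker panel (GRCh37/hg19 coordinates)
# orientation target-unmethylated: ISUS, low beta in the target subtype only
# orientation target-methylated: opposing mdNLR sets (neutrophil / pan-lymphocyte)
# beta_cases / beta_controls: published retrospective group mean betas (opposing sets only)
probe_id	target	orientation	margin	chrom	pos	gene	genic_region	beta_cases	beta_controls
cg09993145	neutrophil	target-methylated	NA	1	25291905	RUNX3	TSS1500	0.56	0.51
cg10825315	neutrophil	target-methylated	NA	14	81425912	TSHR	Body	0.43	0.40
cg23954655	neutrophil	target-methylated	NA	13	99223562	STK24	Body	0.48	0.44
cg04552418	pan-lymphocyte	target-methylated	NA	1	31956405	NA	Intergenic	0.36	0.41
cg13580758	pan-lymphocyte	target-methylated	NA	4	57824450	REST	Body	0.36	0.40
cg26942829	pan-lymphocyte	target-methylated	NA	6	13408158	GFOD1	Body	0.36	0.40
cg07721872	B	target-unmethylated	NA	16	87735256	LOC100129637	Body	NA	NA
cg04838847	B	target-unmethylated	NA	8	110587155	GOLSYN	Body	NA	NA
cg27565966	B	target-unmethylated	NA	16	28943198	CD19	TSS200	NA	NA
cg23244761	Mono	target-unmethylated	NA	6	161796850	PARK2	Body	NA	NA
cg05923857	Mono	target-unmethylated	NA	10	114911615	TCF7L2	Body	NA	NA
cg24788483	Mono	target-unmethylated	NA	10	114911652	TCF7L2	Body	NA	NA
cg05617307	TCD4	target-unmethylated	NA	10	121413182	BAG3	Body	NA	NA
cg14477767	TCD4	target-unmethylated	NA	4	170195438	NA	Intergenic	NA	NA
cg20737812	TCD4	target-unmethylated	NA	15	86336631	KLHL25	5'UTR	NA	NA
cg18857618	TCD8	target-unmethylated	NA	2	87048489	CD8B	Body	NA	NA
cg00219921	TCD8	target-unmethylated	NA	2	87012810	CD8A	3'UTR	NA	NA
cg06419846	TCD8	target-unmethylated	NA	11	66083697	CD248	1stExon	NA	NA
cg25006077	Neu	target-unmethylated	NA	3	152176018	MBNL1	Body	NA	NA
cg25739938	Neu	target-unmethylated	NA	2	9528072	CPSF3	Body	NA	NA
cg05398700	Neu	target-unmethylated	NA	14	102677141	WDR20	Body	NA	NA
cg08326410	NK	target-unmethylated	NA	19	55314884	KIR2DL4	TSS200	NA	NA
cg23855986	NK	target-unmethylated	NA	11	129980502	APLP2	Body	NA	NA
cg23060465	NK	target-unmethylated	NA	8	141625545	EIF2C2	Body	NA	NA
cg04920616	Treg	target-unmethylated	NA	X	49121288	FOXP3	TSS200	NA	NA
cg02033323	Treg	target-unmethylated	NA	X	49005257	FOXP3	5'UTR	NA	NA
cg07499259	Treg	target-unmethylated	NA	1	12188502	TNFRSF8	Body	NA	NA
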