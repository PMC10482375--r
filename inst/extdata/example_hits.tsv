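# Synthetic miniature hit table (one row per gene, grouped by hit_id).
hit_id	genome_id	replicon_id	system_type	gene_start	gene_end	strand	gene_gc	gene_index
sA1_RM_1	sA1	sA1_chr	RM	4050000	4051100	+	0.71	4050
sA1_RM_1	sA1	sA1_chr	RM	4051200	4052400	+	0.73	4051
sA1_Wadjet_1	sA1	sA1_chr	Wadjet	7980000	7981000	-	0.58	7980
sA1_Wadjet_1	sA1	sA1_chr	Wadjet	7981100	7982300	-	0.56	7981
sA1_Wadjet_1	sA1	sA1_chr	Wadjet	7982400	7983200	-	0.57	7982
sA1_Lamassu_1	sA1	sA1_chr	Lamassu	7990000	7991500	+	0.55	7990
sA1_Lamassu_1	sA1	sA1_chr	Lamassu	7991600	7992900	+	0.54	7991
sA1_ShosTA_1	sA1	sA1_pls	ShosTA	120000	121200	+	0.60	120
sA2_RM_1	sA2	sA2_chr	RM	3400000	3401100	+	0.72	3400
sA2_RM_2	sA2	sA2_chr	RM	3425000	3426100	-	0.70	3425
sA2_PD-T4-3_1	sA2	sA2_chr	PD-T4-3	1210000	1211000	+	0.52	1210
rB1_RM_1	rB1	rB1_chr	RM	2700000	2701200	+	0.66	2700
eC1_RM_1	eC1	eC1_chr	RM	2300000	2301200	+	0.50	2300
eC1_CRISPR_1	eC1	eC1_chr	CRISPR	3100000	3104000	+	0.49	3100
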