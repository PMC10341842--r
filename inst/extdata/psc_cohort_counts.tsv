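table	variable	category	count	denominator	digits	printed_pct
table1	age	le60	54	179	1	30.2
table1	age	gt60	125	179	1	69.8
table1	sex	men	105	179	1	58.7
table1	sex	women	74	179	1	41.3
table1	histology	pleomorphic_carcinoma	116	179	1	64.8
table1	histology	spindle_cell_carcinoma	42	179	1	23.5
table1	histology	giant_cell_carcinoma	16	179	1	8.9
table1	histology	carcinosarcoma	5	179	1	2.8
table1	histology	pulmonary_blastoma	0	179	1	0.0
table1	grading	G1	0	179	1	0.0
table1	grading	G2	1	179	1	0.6
table1	grading	G3	173	179	1	96.6
table1	grading	G4	5	179	1	2.8
table1	stage_available	staged	177	179	1	98.9
table1	stage	IA1	4	177	1	2.3
table1	stage	IA2	3	177	1	1.7
table1	stage	IA3	3	177	1	1.7
table1	stage	IB	13	177	1	7.3
table1	stage	IIA	7	177	1	4.0
table1	stage	IIB	24	177	1	13.6
table1	stage	IIIA	33	177	1	18.6
table1	stage	IIIB	16	177	1	9.0
table1	stage	IIIC	1	177	1	0.6
table1	stage	IVA	50	177	1	28.2
table1	stage	IVB	23	177	1	13.0
table1	smoker_available	documented	135	179	1	75.4
table1	smoker	never	20	135	1	14.8
table1	smoker	former	59	135	1	43.7
table1	smoker	current	56	135	1	41.5
section2.1	stage_group	advanced	90	177	1	50.8
section2.1	stage_group	early	87	177	1	NA
section2.1	distant_metastases	present	74	177	1	41.2
section2.1	smoker_ever	former_or_current	115	135	1	85.2
section2.2	tps	negative	32	179	1	17.9
section2.2	tps	positive_ge1	147	179	1	82.1
section2.2	tps	high_ge50	106	179	1	59.2
section2.3	molecular	available	175	179	1	97.8
section2.3	alterations	any	155	175	1	88.6
section2.3	alterations	none	20	175	1	11.4
section2.3	gene	TP53	111	175	1	63.4
section2.3	gene	TP53_sole	34	175	1	19.4
section2.4	actionable	approved_option	62	175	1	35.4
section2.4	gene	EGFR	3	175	1	1.7
section2.4	gene	KRAS	59	175	1	33.7
section2.4	gene	BRAF	7	175	1	4.0
section2.4	gene	MET_ex14	24	175	1	13.7
section2.5	pdl1_high	dna_rna_available	102	106	1	96.2
section2.5	pdl1_high	any_alteration	93	102	1	91.2
section2.5	pdl1_high	actionable	34	102	1	33.3
section2.5	pdl1_high	MET_ex14	12	102	1	11.8
section2.5	pdl1_high	KRAS_G12C	19	102	1	18.6
section2.5	kras_pdl1_high	G12C_fraction	19	44	1	43.2
section2.5	pdl1_ge50_of	KRAS_G12C_patients	19	25	0	76
section2.5	pdl1_ge50_of	MET_ex14_patients	12	24	0	50
section2.6.1	mutations	processing	146	302	1	48.3
section2.6.1	altered_epitopes	lost_binding	2610	3623	0	72
section2.6.1	altered_epitopes	bound_not_immunogenic	1013	3623	0	28
table2	pdl1	ge50	106	179	1	59.2
table2	pdl1_high	dna_rna_available	102	106	1	96.2
table2	pdl1_high	ge1_mutation_or_fusion	93	102	1	91.2
table2	pdl1_high	none	9	102	1	8.8
table2	pdl1_high	KRAS_G12C	19	102	1	18.6
table2	pdl1_high	MET_Ex14skip	12	102	1	11.8
table2	pdl1_high	BRAF_V600E	1	102	1	1.0
table2	pdl1_high	CCDC6_RET_fusion	1	102	1	1.0
table2	pdl1_high	EML4_ALK_fusion	1	102	1	1.0
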