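sample_id	primary_site	stage	er_status	cn_wgs	cn_ddpcr	structure	n_segments
m-218	Colon	IV	unknown	17	20	DM	3
m-215	Breast	IV	-	22	17	DM	6
p-103	Breast	LR	+	16	43	DM	2
m-119	Breast	IV	+	7	9	DM	10
p-6890	Gastric	IV	unknown	84	106	ID	18
p-104	Gastric	IIIA	unknown	19	33	ID	1
p-8191	Gastric	IIIC	unknown	38	70	ID	2
p-2	Breast	IIA	-	21	67	ID	1
p-6	Breast	IIIC	-	20	70	ID	1
p-20	Breast	IIB	-	15	22	ID	1
p-22	Breast	IIA	-	29	140	ID	1
p-23	Breast	LR	-	29	44	ID	1
p-108	Breast	LR	-	22	20	ID	1
p-114	Breast	IIA	-	39	25	ID	3
p-216	Breast	IA	-	23	27	ID	1
p-5	Breast	IIB	+	16	32	ID	1
m-12	Breast	IV	+	16	14	ID	4
p-13	Breast	IIA	+	19	44	ID	1
p-27	Breast	IIA	+	29	28	ID	1
p-29	Breast	IV	+	30	25	ID	7
p-30	Breast	IA	+	12	21	ID	1
p-33	Breast	IIB	+	26	36	ID	1
p-112	Breast	IIA	+	17	51	ID	1
p-203	Breast	IIB	+	21	24	ID	1
p-204	Breast	IIIA	+	13	9	ID	1
p-205	Breast	IIIA	+	9	12	ID	1
p-217	Breast	IV	+	20	37	ID	1
p-102	Breast	IA	unknown	8	22	ID	1
p-16	Breast	IIA	-	15	51	NA	1
p-21	Breast	IIB	-	9	10	NA	1
p-25	Breast	IIB	-	15	21	NA	1
p-28	Breast	IA	-	12	15	NA	1
p-106	Breast	IIA	-	9	47	NA	1
p-115	Breast	IIA	-	12	15	NA	1
p-214	Breast	IIA	-	7	13	other	1
p-3	Breast	IIA	+	13	34	NA	1
p-8	Breast	IA	+	9	13	NA	1
m-11	Breast	IV	+	16	126	NA	1
p-17	Breast	IIA	+	10	90	NA	1
p-209	Breast	IIB	+	10	17	other	1
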