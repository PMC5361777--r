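family	F	M	F_M	FD	UF	FD_UF	SG	MG	SG_MG	total
I1	2	8	11	8	1	12	3	2	6	21
I2	69	35	73	102	30	45	60	14	27	177
I4	33	57	31	87	12	21	12	10	26	122
I8	6	2	9	6	2	9	5	0	5	17
I21	0	0	1	0	0	1	0	0	1	1
I25	6	10	12	17	0	11	3	3	9	28
I29	7	7	1	12	1	2	1	4	1	15
I31	2	0	4	3	1	2	0	1	4	6
I32	0	0	2	0	0	2	0	0	2	2
I35	1	0	0	0	0	1	0	0	1	1
I39	13	2	13	14	4	10	8	5	9	28
I43	17	10	7	14	11	9	8	7	3	34
I51	0	9	5	9	0	5	1	0	4	14
I63	8	8	32	9	9	30	0	12	7	48
I68	1	-	-	-	-	-	1	-	-	1
Total	164	148	202	282	71	160	101	59	105	515
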