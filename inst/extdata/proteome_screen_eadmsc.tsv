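rank	protein_id	gene	diff_adsc_ad	diff_adsc_ob	diff_ad_ob	anova_p
1	F6RYC9	FMC1	0.09	203.33	203.25	0.71
2	F6VEQ6	BCKDK	1.41	841.22	839.81	0.61
3	F6S466	n.r.	2.45	362.92	360.47	0.10
4	F7C673	ARHGAP12	2.66	25.72	28.38	0.99
5	F7DQ27	GLMN	2.81	439.74	436.94	0.63
6	F7DY57	SLC12A5	3.41	152.02	148.61	0.64
7	F6QJT2	TWSG1	6.43	122.23	115.80	0.99
8	F7CVS4	EHD3	6.89	76.78	83.66	0.91
9	F6XYF8	TRIM26	7.04	506.65	499.61	0.46
10	F6SKN5	LRSAM1	7.34	77.12	69.78	0.85
11	F6PTR6	PPP1R9B	7.50	3534.30	3526.79	0.37
12	F7D5F3	SDHC	7.69	159.14	166.82	0.82
13	F7A2B6	CHM	7.71	339.83	347.55	0.77
14	F6QAL5	EPHA2	8.22	1153.61	1161.84	0.73
15	F6SG13	MPHOSPH8	9.24	51.53	60.77	0.96
16	F6R625	CCDC97	9.25	159.47	168.72	0.36
17	F6TZB2	NRBP1	9.43	64.97	74.40	0.99
18	H9H022	PHF8	9.46	50.95	60.41	0.70
19	F6V860	PPP6R1	9.78	27.80	37.58	0.86
20	F6PMV9	IRGQ	10.82	278.48	267.66	0.79
21	F6WE69	ARHGEF12	11.16	86.06	74.90	0.95
22	F6T4G5	DCAF8	12.01	883.61	895.62	0.77
23	F7DNN2	COQ4	12.08	488.65	476.57	0.23
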