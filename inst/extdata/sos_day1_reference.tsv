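gene	probe	fc_day1	auc	cutoff	sensitivity_pct	specificity_pct	lr_pos	lr_neg	ppv_pct	npv_pct
CETP	A_23_P49376	4.95	0.91	-0.64	83.87	71.79	2.97	0.22	90.35	57.14
ITGB3	A_24_P318656	7.47	0.87	-0.94	85.48	71.79	3.03	0.20	90.60	63.04
NEXN	A_33_P3341429	4.24	0.86	-0.51	83.87	76.92	3.63	0.21	92.04	60.00
PLXNB3	A_33_P3413038	5.10	0.85	-0.59	83.06	81.58	4.51	0.21	92.45	57.63
CMTM5	A_23_P106042	4.93	0.85	-0.81	85.48	64.10	2.38	0.23	88.33	58.14
MMRN1	A_33_P3212257	4.66	0.85	-0.59	83.06	82.05	4.63	0.21	93.64	83.78
ITGA2B	A_24_P65373	4.89	0.84	-1.37	85.48	64.10	2.38	0.23	88.33	58.14
PF4	A_24_P79403	3.59	0.84	-0.66	85.48	61.54	2.22	0.24	87.60	57.14
MYL9	A_23_P210425	5.55	0.83	-1.53	85.48	61.54	2.22	0.24	87.60	59.52
PPBP	A_23_P121596	4.36	0.83	-0.94	85.48	58.97	2.08	0.25	87.50	55.81
TREML1	A_33_P3381777	4.10	0.82	-1.35	85.48	48.72	1.67	0.30	84.13	56.76
LCN2	A_23_P169437	3.60	0.82	-1.24	85.48	61.54	2.22	0.24	88.33	57.14
NEXN	A_23_P200001	2.37	0.82	-0.24	82.26	66.67	2.47	0.27	88.70	54.17
LCN15	A_33_P3263938	2.02	0.68	-2.52	85.48	20.51	1.08	0.71	77.37	30.77
PLA2G7	A_23_P145096	-7.09	0.90	1.00	85.48	82.05	4.76	0.18	64.00	93.81
MPP3	A_23_P141345	-3.28	0.89	0.67	82.05	83.87	5.09	0.21	61.54	93.69
ARHGEF10L	A_33_P3799936	-3.86	0.88	0.64	85.48	66.67	2.56	0.22	59.09	86.55
GPR124	A_23_P43276	-3.34	0.86	0.93	85.48	64.10	2.38	0.23	58.14	88.33
APCDD1	A_23_P337262	-3.66	0.84	0.33	87.18	66.13	2.57	0.19	44.74	94.25
ARHGEF10L	A_33_P3215575	-2.81	0.81	-0.20	87.18	64.06	2.43	0.20	51.25	94.25
MYCL	A_33_P3306068	-2.95	0.81	0.51	85.94	66.67	2.58	0.21	36.95	93.33
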