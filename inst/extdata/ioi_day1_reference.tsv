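gene	probe	fc_day1	auc	cutoff	sensitivity_pct	specificity_pct	lr_pos	lr_neg	ppv_pct	npv_pct
ADM	A_23_P127948	12.95	0.9988	-1.928	98.80	96.67	29.67	0.01	99.40	93.55
FAM20A	A_32_P108254	55.35	0.9982	-2.339	97.60	96.67	29.31	0.02	98.76	77.78
ITGA7	A_23_P128084	15.67	0.9968	-2.314	95.81	96.67	28.77	0.04	99.38	80.56
FAM20A	A_24_P352952	26.69	0.9950	-1.842	94.01	96.67	28.23	0.06	100.00	78.95
TDRD9	A_32_P208350	14.53	0.9914	-1.756	93.41	96.67	28.05	0.07	99.36	75.00
IL10	A_23_P126735	7.06	0.9912	-0.674	89.22	96.67	26.79	0.11	99.33	61.70
MMP9	A_23_P40174	45.49	0.9906	-3.073	95.81	96.67	28.77	0.04	99.38	80.56
CD177	A_23_P259863	110.31	0.9876	-1.891	88.02	96.67	26.43	0.12	99.31	53.85
BMX	A_23_P253602	28.57	0.9816	-2.417	94.61	96.67	28.41	0.06	99.37	76.32
CD177	A_21_P0011751	100.99	0.9804	-1.839	85.63	96.67	25.71	0.15	100.00	56.60
HPR	A_23_P206760	18.26	0.9766	-2.407	93.41	96.67	28.05	0.07	99.36	72.50
DACH1	A_33_P3316786	4.58	0.9756	-1.209	94.61	96.67	28.41	0.06	99.37	78.95
CYP19A1	A_23_P37410	9.68	0.9729	-1.069	86.83	96.67	26.08	0.14	99.32	56.86
DACH1	A_23_P32577	5.73	0.9729	-1.649	95.81	90.00	9.58	0.05	98.16	79.41
IGFBP2	A_23_P119943	12.73	0.9695	-1.533	85.63	96.67	25.71	0.15	99.30	54.72
ALPL	A_24_P353619	9.86	0.9685	-1.383	86.23	96.67	25.89	0.14	99.31	55.77
OLAH	A_23_P161458	26.15	0.9633	-2.885	90.42	96.67	27.15	0.10	99.34	64.44
CYP19A1	A_33_P3351371	7.34	0.9627	-0.888	85.03	96.67	25.53	0.15	100.00	54.55
ILR1	A_33_P3396389	8.06	0.9495	-1.821	90.42	90.00	9.04	0.11	100.00	54.55
OLAH	A_33_P3317109	9.98	0.9441	-1.493	85.63	96.67	25.71	0.15	99.31	56.60
ILR1	A_24_P200023	8.25	0.9421	-1.525	86.83	96.67	26.08	0.14	99.32	56.86
MMP8	A_23_P24493	6.77	0.9329	-1.608	85.63	86.67	6.42	0.17	97.96	52.00
TGFA	A_23_P377291	3.93	0.9327	-0.945	85.03	83.33	5.10	0.18	42.65	42.65
IL1R2	A_24_P63019	17.29	0.9323	-1.928	85.63	93.33	12.84	0.15	88.62	53.85
CD177	A_33_P3232080	6.23	0.9104	-1.303	85.03	90.00	8.50	0.17	98.62	46.15
CYP19A1	A_24_P920646	2.36	0.8467	-0.538	85.03	46.67	1.59	0.32	89.81	35.00
CYP19A1	A_32_P86289	2.03	0.8178	-0.552	85.63	43.33	1.51	0.33	90.63	35.14
VSTM1	A_33_P3514487	2.83	0.7721	-1.483	85.63	40.00	1.43	0.36	88.82	33.33
CD177	A_33_P3232086	2.24	0.7621	-0.544	85.63	43.33	1.51	0.33	89.94	34.21
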