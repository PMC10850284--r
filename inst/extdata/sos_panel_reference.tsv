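comparison	cutoff_kind	auc	auc_se	ci90_lower	ci90_upper	cutoff	sensitivity_pct	specificity_pct	lr_pos	lr_neg	ppv_pct	npv_pct
SIRS_vs_Sepsis	ppv95	0.9758	0.01067	0.9582	0.9933	-4.3770	96.80	89.74	9.4347	0.0357	97.60	89.74
SIRS_vs_Sepsis	npv98	0.9758	0.01067	0.9582	0.9933	-6.9830	99.20	64.10	2.7632	0.0125	89.85	96.15
SIRS_vs_ABDM	ppv95	0.9842	0.009643	0.9684	1.0000	-2.5610	90.38	97.44	35.3047	0.0987	97.92	88.37
SIRS_vs_ABDM	npv98	0.9842	0.009643	0.9684	1.0000	-4.1670	98.08	92.31	12.7542	0.0208	94.44	97.30
SIRS_vs_PLMN	ppv95	0.9698	0.01398	0.9468	0.9928	-4.1520	94.52	92.31	12.2913	0.0594	96.00	92.11
SIRS_vs_PLMN	npv98	0.9698	0.01398	0.9468	0.9928	-6.9570	98.63	64.10	2.7474	0.0214	84.88	96.15
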