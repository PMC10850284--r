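name	signature	family	description
ioi_6gene	ADM+CD177+FAM20A+ITGA7+MMP9+OLAH	IoI	Large inflammation-indicator panel, severe inflammation vs healthy controls
ioi_5gene	ADM+FAM20A+OLAH+ITGA7+MMP9	IoI	Five-gene inflammation panel (CD177 removed)
ioi_3gene	ADM+FAM20A+OLAH	IoI	Compact inflammation panel
ioi_2gene	FAM20A+OLAH	IoI	Minimal inflammation panel
sos_5gene	CETP+CMTM5+MIA-MPP3-PLA2G7	SoS	Five-gene SIRS-vs-sepsis discriminator signature
sos_5gene_mia_neg	CMTM5+CETP-PLA2G7-MIA-MPP3	SoS	Variant of sos_5gene with MIA negated (alternative printed orientation)
sos_abdm	CMTM5+ITGB3-PLA2G7-ARHGEF10L-GPR124	SoS	Discriminator variant performing well for abdominal sepsis
septicyte_lab	PLAC8-PLA2G7+LAMP1-CEACAM4	external	Published SeptiCyte Lab sepsis-vs-SIRS signature
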