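CSP	canonical senescence pathway (example subset)	CDKN1A	CDKN2A	TP53	GLB1	RB1	ATM	NFATC2	SERPINE1	MDM2	CDK6	SMAD2	YPEL3	SQSTM1	MRAS	IL15	AXL	PIK3R1	CXCL16
SIP	senescence initiating pathway (example subset)	DDB2	RRM2B	CHEK1	CHEK2	ATR	TP53BP1	H2AX	MDC1	NBN	RAD50	MRE11	BRCA1
SASP	senescence associated secretory phenotype (example subset)	IL6	CXCL8	IL1B	IL1A	CXCL1	CXCL2	MMP3	MMP9	IGFBP3	TNF	CCL2	SERPINE1	PLAU
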