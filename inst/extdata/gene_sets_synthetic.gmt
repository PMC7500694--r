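IMMUNE_RESPONSE	synthetic immune-response category	FCGR1A	SOCS3	CXCR3	IL2RG	TLR7	CCL5	GZMB	CAMP	MX1	OAS1	IFI44L	CD40LG	IL6	TNF	IFNG	IL10	CD19	CD3E	CD8A	FOXP3
IMMUNE_SYSTEM_PROCESS	synthetic immune-system-process category	FCGR1A	SOCS3	CXCR3	IL2RG	TLR7	CCL5	GZMB	CAMP	MX1	OAS1	IFI44L	CD40LG	DPP4	CD99	IL7R	STAT1	STAT3	JAK1	JAK3	NFKB1	CD4
DEFENSE_RESPONSE	synthetic defense-response category	CAMP	MX1	OAS1	IFI44L	TLR7	CCL5	GZMB	IFIT1	IFIT3	ISG15	RSAD2	OASL	BST2	IFI6
Y_CHROMOSOME_GENES	synthetic Y-linked category	RPS4Y1	RPS4Y2	KDM5D	DDX3Y	UTY	USP9Y	EIF1AY	NLGN4Y	TXLNGY	ZFY	PRKY	TMSB4Y	SRY	AMELY
X_INACTIVATION_ESCAPE	synthetic X-escape category	XIST	KDM6A	ZFX	DDX3X	EIF1AX	PUDP	STS	JPX	FTX
CHEMOKINE_SIGNALING	synthetic chemokine category	CCL5	CXCR3	CCR5	CXCL9	CXCL10	CXCL11	CCL2	CCL3	CCL4
PEPTIDASE_ACTIVITY	synthetic peptidase category	DPP4	USP9Y	GZMB	CAMP	MMP9	ELANE	CTSG	PRTN3
CELL_CYCLE	synthetic unrelated category	CDK1	CDK2	CCNB1	CCNA2	PLK1	AURKA	AURKB	BUB1	MCM2	MCM3	PCNA	E2F1
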