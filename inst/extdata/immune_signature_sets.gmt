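IFNG_RESPONSE	interferon-gamma response program (inflamed)	STAT1	IRF1	GBP1	GBP5	IDO1	CXCL9	CXCL10	CXCL11	IFNG	IL2RG	CIITA	SOCS1	JAK2	PSMB9	TAP1
ANTIGEN_PRESENTATION	MHC class I/II antigen processing and presentation (inflamed)	HLA-A	HLA-B	HLA-C	B2M	TAP1	TAP2	TAPBP	PSMB8	PSMB9	PSMB10	HLA-DRA	HLA-DRB1	HLA-DQA1	HLA-E	NLRC5
TLS_B_CELL	B-cell and tertiary-lymphoid-structure program (inflamed)	CD19	MS4A1	CD79A	CD79B	CXCL13	CCL19	CCL21	CCR7	CD27	CD38	POU2AF1	TNFRSF13B	FCRL5	BLK
TIL_CYTOTOXIC	cytotoxic tumor-infiltrating lymphocyte and PD-L1 program (inflamed)	CD8A	CD3D	CD3E	CD2	GZMA	GZMB	PRF1	CCL5	NKG7	LAG3	TIGIT	PDCD1	CD274	CXCR6	CMKLR1	PDCD1LG2
TGFB_SIGNALING	TGF-beta signaling and reactive stroma (immune excluded)	TGFB1	TGFB2	TGFB3	TGFBR1	TGFBR2	SMAD2	SMAD3	SMAD4	SERPINE1	THBS1	ACTA2	COL4A1	TAGLN	FN1	ZEB1
ANGIOGENESIS	tumor angiogenesis program (immune excluded)	VEGFA	VEGFB	VEGFC	FLT1	KDR	PECAM1	CDH5	ANGPT2	TEK	ESM1	CD34	VWF	PDGFB	NOTCH4	DLL4
FATTY_ACID_METABOLISM	fatty-acid synthesis and beta-oxidation (immune desert)	FASN	ACACA	ACACB	CPT1A	CPT2	ACOX1	SCD	ELOVL6	HADHA	HADHB	ACADM	ACADL	ECHS1	ACAA2	SLC27A2
NEUROENDOCRINE	neuroendocrine differentiation markers (immune desert)	CHGA	CHGB	SYP	ENO2	NCAM1	ASCL1	INSM1	SCG2	SCG3	PCSK1	PCSK2	TUBB3	ELAVL4	DDC
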