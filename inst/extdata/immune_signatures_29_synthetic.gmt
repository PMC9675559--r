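ACTIVATED_CD8_T_CELLS	synthetic	CD8A	GZMA	GZMB	PRF1	IFNG	NKG7
B_CELLS	synthetic	CD19	MS4A1	CD79A	CD79B	BLK
CYTOTOXIC_CELLS	synthetic	GZMA	GZMH	KLRB1	KLRD1	NKG7	PRF1
DENDRITIC_CELLS	synthetic	CCL13	CD209	HSD11B1	NPR1
NK_CELLS	synthetic	KIR2DL3	KIR3DL1	NCR1	XCL1	XCL2
MACROPHAGES	synthetic	CD68	CD163	MSR1	MRC1
MAST_CELLS	synthetic	TPSAB1	TPSB2	CPA3	MS4A2
NEUTROPHILS	synthetic	FCGR3B	CSF3R	S100A12	CEACAM3
T_HELPER_CELLS	synthetic	CD4	IL7R	CD28	ICOS
TH1_CELLS	synthetic	TBX21	IFNG	IL12RB2	STAT1	CXCR3
TH2_CELLS	synthetic	GATA3	IL4	IL5	CCR4
TH17_CELLS	synthetic	RORC	IL17A	IL23R	CCR6
TREG_CELLS	synthetic	FOXP3	IL2RA	CTLA4	IKZF2
TFH_CELLS	synthetic	CXCR5	BCL6	ICOS	PDCD1
GAMMA_DELTA_T_CELLS	synthetic	TRGC1	TRGC2	TRDC
CD8_T_EFFECTOR_MEMORY	synthetic	CD8A	EOMES	GZMK	CCR7
IMMATURE_DENDRITIC_CELLS	synthetic	CD1A	CD1B	CD1E	F13A1
PLASMACYTOID_DENDRITIC_CELLS	synthetic	IL3RA	CLEC4C	LILRA4
ANTIGEN_PRESENTATION	synthetic	HLA-DQA1	HLA-DRB1	HLA-E	TAP1	TAP2	B2M
CHECKPOINT_MOLECULES	synthetic	CD274	PDCD1	PDCD1LG2	CTLA4	LAG3	TIGIT	HAVCR2
COSTIMULATORY_APC	synthetic	CD80	CD86	CD40	ICOSLG
COSTIMULATORY_T_CELL	synthetic	CD27	CD28	TNFRSF9	TNFRSF18
CYTOLYTIC_ACTIVITY	synthetic	GZMA	PRF1
INFLAMMATION_PROMOTING	synthetic	IL1A	IL1B	IL6	CXCL9	CXCL10	TNF
INTERFERON_RESPONSE	synthetic	STAT1	IRF1	ISG15	MX1	OAS1	IDO1
MHC_CLASS_I	synthetic	HLA-A	HLA-B	HLA-C	B2M	TAP1
PARAINFLAMMATION	synthetic	PLAT	PTGS2	CXCL9	ISG15
T_CELL_COINHIBITION	synthetic	BTLA	VSIR	CD160	LAG3
CHEMOKINE_RECEPTORS	synthetic	CCL5	CXCR6	CMKLR1	CXCR3	CCR5
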