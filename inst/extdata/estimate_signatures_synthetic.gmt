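STROMAL_SIGNATURE	synthetic	COL1A1	COL1A2	COL3A1	COL5A1	FAP	THY1	DCN	LUM	POSTN	FBN1	ACTA2	PDGFRB	SPARC	FN1	VIM	TAGLN	MMP2	TIMP2	CDH11	FGF7
IMMUNE_SIGNATURE	synthetic	PTPRC	CD2	CD3D	CD3E	CD8A	CD19	MS4A1	CCL5	CXCL9	GZMA	GZMB	PRF1	IL7R	LCK	ZAP70	CD27	TIGIT	LAG3	NKG7	STAT1
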