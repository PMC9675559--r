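FERROPTOSIS_DRIVER	synthetic	ACSL4	ALOX15	ALOX12	TFRC	NCOA4	LPCAT3	GLS2	SAT1	HMOX1	PEBP1	ELOVL5	FADS2
FERROPTOSIS_SUPPRESSOR	synthetic	GPX4	SLC7A11	FTH1	FTL	NFE2L2	AIFM2	SCD	ACSL3	HSPB1	SQLE	HMGCR	FDFT1
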