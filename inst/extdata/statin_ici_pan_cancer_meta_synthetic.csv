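study_id,hr,ci_lower,ci_upper,n,subgroup
ICI_STUDY_A,0.70,0.52,0.94,350,immunotherapy
ICI_STUDY_B,0.82,0.60,1.12,420,immunotherapy
ICI_STUDY_C,0.64,0.43,0.95,310,immunotherapy
ICI_STUDY_D,0.88,0.68,1.14,505,immunotherapy
ICI_STUDY_E,0.59,0.38,0.92,280,immunotherapy
ICI_STUDY_F,0.76,0.51,1.13,270,immunotherapy
INHOUSE_COHORT,0.55,0.31,0.98,101,immunotherapy
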