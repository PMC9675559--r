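study_id,hr,ci_lower,ci_upper,n,subgroup
NSCLC_STUDY_01,0.81,0.74,0.89,12000,non-immunotherapy
NSCLC_STUDY_02,0.88,0.79,0.98,9500,non-immunotherapy
NSCLC_STUDY_03,0.79,0.70,0.89,8400,non-immunotherapy
NSCLC_STUDY_04,0.92,0.81,1.04,7200,non-immunotherapy
NSCLC_STUDY_05,0.85,0.74,0.98,6100,non-immunotherapy
NSCLC_STUDY_06,0.77,0.66,0.90,5300,non-immunotherapy
NSCLC_STUDY_07,0.90,0.76,1.07,4200,non-immunotherapy
NSCLC_STUDY_08,0.83,0.69,1.00,3500,non-immunotherapy
NSCLC_STUDY_09,0.95,0.78,1.16,2800,non-immunotherapy
NSCLC_STUDY_10,0.72,0.56,0.93,1500,non-immunotherapy
NSCLC_STUDY_11,0.68,0.49,0.94,900,immunotherapy
NSCLC_STUDY_12,0.74,0.52,1.05,700,immunotherapy
NSCLC_STUDY_13,0.66,0.43,1.01,450,immunotherapy
NSCLC_STUDY_14,0.80,0.49,1.31,300,immunotherapy
NSCLC_STUDY_15,0.62,0.36,1.07,250,immunotherapy
NSCLC_STUDY_16,0.71,0.39,1.29,173,immunotherapy
INHOUSE_COHORT,0.55,0.31,0.98,101,immunotherapy
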