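modelled_name	cms_condition	cms_weight	recovery_rule	can_recur	is_cancer	sex_specific	past_self_as_risk	past_self_rr	recovery_prob
dementia	dementia	2.50	none	FALSE	FALSE	both	FALSE	NA	NA
breast_cancer	cancer	1.53	cancer_10yr	FALSE	TRUE	female	FALSE	NA	NA
colorectal_cancer	cancer	1.53	cancer_10yr	FALSE	TRUE	both	FALSE	NA	NA
lung_cancer	cancer	1.53	cancer_10yr	FALSE	TRUE	both	FALSE	NA	NA
prostate_cancer	cancer	1.53	cancer_10yr	FALSE	TRUE	male	FALSE	NA	NA
other_cancers	cancer	1.53	cancer_10yr	TRUE	TRUE	both	FALSE	NA	NA
copd	copd	1.46	none	FALSE	FALSE	both	FALSE	NA	NA
atrial_fibrillation	atrial_fibrillation	1.34	none	FALSE	FALSE	both	FALSE	NA	NA
heart_failure	heart_failure	1.18	none	FALSE	FALSE	both	FALSE	NA	NA
constipation	constipation	1.12	stochastic	TRUE	FALSE	both	TRUE	2.0	0.30
epilepsy	epilepsy	0.92	none	FALSE	FALSE	both	FALSE	NA	NA
chronic_pain	chronic_pain	0.92	stochastic	TRUE	FALSE	both	TRUE	2.0	0.20
stroke_tia	stroke_tia	0.80	none	FALSE	FALSE	both	FALSE	NA	NA
diabetes_type1	diabetes	0.75	none	FALSE	FALSE	both	FALSE	NA	NA
diabetes_type2	diabetes	0.75	none	FALSE	FALSE	both	FALSE	NA	NA
alcohol_problems	alcohol_problems	0.65	stochastic	TRUE	FALSE	both	TRUE	2.0	0.25
psychosis_bipolar	psychosis_bipolar	0.64	none	FALSE	FALSE	both	FALSE	NA	NA
chronic_kidney_disease	chronic_kidney_disease	0.53	none	FALSE	FALSE	both	FALSE	NA	NA
anxiety_depression	anxiety_depression	0.50	stochastic	TRUE	FALSE	both	TRUE	2.5	0.35
coronary_heart_disease	coronary_heart_disease	0.49	none	FALSE	FALSE	both	FALSE	NA	NA
rheumatoid_arthritis	connective_tissue	0.43	none	FALSE	FALSE	both	FALSE	NA	NA
other_connective_tissue	connective_tissue	0.43	none	FALSE	FALSE	both	FALSE	NA	NA
irritable_bowel_syndrome	irritable_bowel_syndrome	0.21	none	FALSE	FALSE	both	FALSE	NA	NA
asthma	asthma	0.19	stochastic	TRUE	FALSE	both	TRUE	2.0	0.10
hearing_loss	hearing_loss	0.09	none	FALSE	FALSE	both	FALSE	NA	NA
hypertension	hypertension	0.08	none	FALSE	FALSE	both	FALSE	NA	NA
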