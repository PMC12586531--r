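modelled_name	inc_rate60	inc_age_ln	inc_dimd_ln	inc_trend_ln	trend_rule	cf_rate60	cf_age_ln	cf_trend_ln	prev60	prev_age_ln	prev_min_age
dementia	0.0015	0.140	0.030	0.000	log_linear	0.150	0.060	-0.005	0.008	0.150	60
breast_cancer	0.0025	0.020	0.000	-0.002	log_linear	0.030	0.040	-0.008	0.020	0.030	40
colorectal_cancer	0.0012	0.060	0.010	-0.002	log_linear	0.050	0.050	-0.008	0.010	0.060	40
lung_cancer	0.0008	0.070	0.060	-0.004	log_linear	0.250	0.030	-0.008	0.003	0.060	40
prostate_cancer	0.0020	0.090	0.000	-0.002	log_linear	0.040	0.050	-0.008	0.015	0.090	45
other_cancers	0.0040	0.050	0.020	-0.002	log_linear	0.100	0.040	-0.008	0.020	0.050	30
copd	0.0030	0.060	0.080	-0.004	log_linear	0.080	0.060	-0.004	0.040	0.060	35
atrial_fibrillation	0.0040	0.080	0.010	0.000	log_linear	0.040	0.070	-0.005	0.030	0.080	30
heart_failure	0.0030	0.090	0.030	-0.003	log_linear	0.100	0.070	-0.005	0.015	0.090	30
constipation	0.0100	0.030	0.020	0.000	none	0.000	0.000	0.000	0.040	0.030	30
epilepsy	0.0008	0.000	0.020	0.000	log_linear	0.010	0.050	0.000	0.008	0.000	30
chronic_pain	0.0200	0.020	0.060	0.000	frozen	0.000	0.000	0.000	0.150	0.020	30
stroke_tia	0.0030	0.070	0.030	-0.004	log_linear	0.100	0.070	-0.006	0.020	0.070	30
diabetes_type1	0.0003	-0.020	0.010	0.000	log_linear	0.010	0.050	-0.003	0.005	0.000	30
diabetes_type2	0.0080	0.030	0.060	0.010	log_linear	0.015	0.060	-0.004	0.080	0.040	30
alcohol_problems	0.0030	-0.020	0.100	0.000	log_linear	0.010	0.020	0.000	0.020	-0.010	30
psychosis_bipolar	0.0006	-0.010	0.080	0.000	log_linear	0.010	0.020	0.000	0.008	0.000	30
chronic_kidney_disease	0.0040	0.080	0.030	0.000	log_linear	0.030	0.070	-0.004	0.030	0.080	30
anxiety_depression	0.0150	-0.010	0.050	0.000	none	0.002	0.030	0.000	0.100	-0.010	30
coronary_heart_disease	0.0050	0.060	0.050	-0.005	log_linear	0.050	0.070	-0.006	0.050	0.060	30
rheumatoid_arthritis	0.0008	0.010	0.010	0.000	log_linear	0.005	0.050	0.000	0.010	0.020	30
other_connective_tissue	0.0008	0.010	0.010	0.000	log_linear	0.003	0.050	0.000	0.010	0.020	30
irritable_bowel_syndrome	0.0040	-0.010	0.010	0.000	log_linear	0.000	0.000	0.000	0.040	-0.010	30
asthma	0.0030	-0.010	0.030	0.000	log_linear	0.002	0.040	0.000	0.060	-0.010	30
hearing_loss	0.0060	0.080	0.010	0.000	log_linear	0.000	0.000	0.000	0.050	0.080	30
hypertension	0.0150	0.040	0.020	-0.002	log_linear	0.001	0.050	0.000	0.250	0.040	30
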