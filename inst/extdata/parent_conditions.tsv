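condition	parent	rr
dementia	stroke_tia	1.8
dementia	diabetes_type2	1.5
breast_cancer	diabetes_type2	1.2
colorectal_cancer	diabetes_type2	1.3
lung_cancer	copd	1.9
other_cancers	diabetes_type2	1.2
atrial_fibrillation	coronary_heart_disease	1.8
atrial_fibrillation	hypertension	1.5
heart_failure	coronary_heart_disease	2.5
heart_failure	atrial_fibrillation	1.9
heart_failure	hypertension	1.6
constipation	anxiety_depression	1.3
epilepsy	stroke_tia	2.5
chronic_pain	rheumatoid_arthritis	1.8
chronic_pain	anxiety_depression	1.4
stroke_tia	atrial_fibrillation	2.5
stroke_tia	diabetes_type2	1.8
stroke_tia	hypertension	1.6
psychosis_bipolar	anxiety_depression	1.5
anxiety_depression	chronic_pain	1.6
anxiety_depression	coronary_heart_disease	1.3
coronary_heart_disease	diabetes_type2	1.9
coronary_heart_disease	hypertension	1.6
coronary_heart_disease	chronic_kidney_disease	1.5
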