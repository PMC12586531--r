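exposure	condition	form	rr_per_unit	unit	lag_years	cumulative	affects_case_fatality	affects_nonmodelled_mortality
bmi	dementia	log_linear_continuous	1.060	kg/m2	5	FALSE	TRUE	FALSE
smoking	dementia	smoking_status	1.60	status	5	FALSE	TRUE	TRUE
pa	breast_cancer	log_linear_continuous	1.050	days/week	9	FALSE	TRUE	TRUE
bmi	breast_cancer	log_linear_continuous	1.050	kg/m2	9	FALSE	TRUE	FALSE
smoking	breast_cancer	smoking_status	1.30	status	9	TRUE	TRUE	TRUE
ets	breast_cancer	categorical	1.10	binary	9	FALSE	TRUE	FALSE
pa	colorectal_cancer	log_linear_continuous	1.060	days/week	9	FALSE	TRUE	TRUE
bmi	colorectal_cancer	log_linear_continuous	1.050	kg/m2	9	FALSE	TRUE	FALSE
smoking	colorectal_cancer	smoking_status	1.40	status	9	TRUE	TRUE	TRUE
smoking	lung_cancer	smoking_status	3.00	status	9	TRUE	TRUE	TRUE
ets	lung_cancer	categorical	1.25	binary	9	FALSE	TRUE	FALSE
fruit	lung_cancer	log_linear_continuous	1.0008	g/day	9	FALSE	TRUE	FALSE
smoking	prostate_cancer	smoking_status	1.20	status	9	FALSE	TRUE	TRUE
smoking	copd	smoking_status	3.00	status	5	TRUE	TRUE	TRUE
ets	copd	categorical	1.15	binary	5	FALSE	TRUE	FALSE
bmi	atrial_fibrillation	log_linear_continuous	1.070	kg/m2	5	FALSE	TRUE	FALSE
smoking	atrial_fibrillation	smoking_status	1.30	status	5	FALSE	TRUE	TRUE
sbp	atrial_fibrillation	log_linear_continuous	1.020	mmHg	5	FALSE	TRUE	TRUE
pa	stroke_tia	log_linear_continuous	1.070	days/week	5	FALSE	TRUE	TRUE
bmi	stroke_tia	log_linear_continuous	1.060	kg/m2	5	FALSE	TRUE	FALSE
smoking	stroke_tia	smoking_status	1.90	status	5	FALSE	TRUE	TRUE
ets	stroke_tia	categorical	1.20	binary	5	FALSE	TRUE	FALSE
sbp	stroke_tia	log_linear_continuous	1.030	mmHg	5	FALSE	TRUE	TRUE
fruit	stroke_tia	log_linear_continuous	1.0010	g/day	5	FALSE	TRUE	FALSE
veg	stroke_tia	log_linear_continuous	1.0010	g/day	5	FALSE	TRUE	FALSE
tchol	stroke_tia	log_linear_continuous	1.150	mmol/L	5	FALSE	TRUE	FALSE
pa	diabetes_type2	log_linear_continuous	1.100	days/week	5	FALSE	TRUE	TRUE
bmi	diabetes_type2	log_linear_continuous	1.200	kg/m2	5	FALSE	TRUE	FALSE
smoking	diabetes_type2	smoking_status	1.40	status	5	FALSE	TRUE	TRUE
ets	diabetes_type2	categorical	1.10	binary	5	FALSE	TRUE	FALSE
sbp	diabetes_type2	log_linear_continuous	1.010	mmHg	5	FALSE	TRUE	TRUE
fruit	diabetes_type2	log_linear_continuous	1.0005	g/day	5	FALSE	TRUE	FALSE
bmi	chronic_kidney_disease	log_linear_continuous	1.060	kg/m2	5	FALSE	TRUE	FALSE
sbp	chronic_kidney_disease	log_linear_continuous	1.020	mmHg	5	FALSE	TRUE	TRUE
pa	coronary_heart_disease	log_linear_continuous	1.080	days/week	5	FALSE	TRUE	TRUE
bmi	coronary_heart_disease	log_linear_continuous	1.080	kg/m2	5	FALSE	TRUE	FALSE
smoking	coronary_heart_disease	smoking_status	2.00	status	5	FALSE	TRUE	TRUE
ets	coronary_heart_disease	categorical	1.25	binary	5	FALSE	TRUE	FALSE
sbp	coronary_heart_disease	log_linear_continuous	1.025	mmHg	5	FALSE	TRUE	TRUE
fruit	coronary_heart_disease	log_linear_continuous	1.0010	g/day	5	FALSE	TRUE	FALSE
veg	coronary_heart_disease	log_linear_continuous	1.0010	g/day	5	FALSE	TRUE	FALSE
tchol	coronary_heart_disease	log_linear_continuous	1.350	mmol/L	5	FALSE	TRUE	FALSE
bmi	asthma	log_linear_continuous	1.050	kg/m2	5	FALSE	TRUE	FALSE
smoking	asthma	smoking_status	1.50	status	5	FALSE	TRUE	TRUE
sbp	hypertension	log_linear_continuous	1.080	mmHg	5	FALSE	TRUE	TRUE
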