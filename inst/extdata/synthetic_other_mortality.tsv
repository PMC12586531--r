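source_type	source	form	rr_per_unit	lag_years
exposure	sbp	log_linear_continuous	1.010	5
exposure	smoking	smoking_status	1.80	5
exposure	pa	log_linear_continuous	1.080	5
condition	coronary_heart_disease	prevalent	1.60	0
condition	stroke_tia	prevalent	1.70	0
condition	diabetes_type2	prevalent	1.50	0
condition	copd	prevalent	1.80	0
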