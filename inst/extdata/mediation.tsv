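parameter	value	ci_lo	ci_hi	unit
delta_sbp_per_bmi_unit	2.55	1.55	3.54	mmHg per kg/m2
delta_tc_per_bmi_unit	0.23	0.15	0.30	mmol/L per kg/m2
bmi_floor	25	NA	NA	kg/m2
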