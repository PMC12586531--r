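exposure	central	unit	sampling_distribution	support_lo	support_hi
bmi	22	kg/m2	triangular	19.8	24.2
sbp	112	mmHg	triangular	100.8	123.2
tchol	4	mmol/L	triangular	3.6	4.4
fruit	320	g/day	triangular	288	352
veg	320	g/day	triangular	288	352
pa	7	days/week	fixed	7	7
smoking	0	status	fixed	0	0
ets	0	binary	fixed	0	0
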