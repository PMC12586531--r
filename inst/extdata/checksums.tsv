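table	quantity	expected
conditions	n_rows	26
conditions	n_cms_conditions	20
conditions	cms_weight_sum_distinct	16.33
conditions	n_lifelong_cms	14
risk_links	n_rows	45
risk_links	n_cumulative	4
tmrel	n_rows	8
parent_conditions	n_rows	24
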