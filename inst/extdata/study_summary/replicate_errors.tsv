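sample	dilution	mean_n_per_ml	dn_pct	mean_rh_nm	drh_pct
plasma	50	2.78e10	2	75	1
erythrocytes	50	1.33e11	6	94	4
spruce_homogenate	5	5.67e9	38	71	12
p_tricornutum_isolate		1.10e9	9	125	11
liposomes	5e4	1.55e14	4	131	4
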