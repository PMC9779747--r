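sample	fraction	dilution_series	ilm_dilution	n_tracked	ilm_rh_nm	ilm_sd_nm	dls_dilution	dls_rh_small_nm	dls_rh_main_nm	dls_rh_large_nm	dls_lp
B1	IS		40	322	116	36	70
B2	IS		10	320	115	61		10	185	~1000	TRUE
B3	SN		10	333	68	41		7.6	39	~5000
B4	SN			305	103	56		2.7;18	120		TRUE
B5	IS		50	381	103	27		70	153
B6	IS		20
B8	IS			350	119	40
S1	IS			UDL			1000			~1600	TRUE
S6	IS			UDL
S9	IS			61	106	79
S11	IS		3						148
S12	IS			UDL					142
S13	IS		10	1
T1	IS			184	118	79		18	70	~1000
P1	IS
P2	IS
P3	IS			192	193	100			170
P4	IS			101	194	126			190
P11	IS			40	199	126
P12	IS			51	147	93
P16	IS			166	193	113
P21	SN			70	143	98
P26	SN			51	167	122
LA		1000x	5e4	329	152	59	1000	20	189
LB		1000x	2e4	96	147	59	1000	71	235
LC		1000x	2e5	138	136	55	1000	11	122	622
LA		100x	2e5	403	148	54	100	12	150
LB		100x	2e5	342	143	61	100	28	187
LC		100x	2e5	371	152	64	100	30	133	413
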