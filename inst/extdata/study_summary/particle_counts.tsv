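sample	fraction	dilution_series	fcm_dilution	fcm_n_per_ml	ilm_dilution	ilm_n_per_ml	ilm_flags	dls_itot_khz_mw	dls_frac1	dls_frac2	dls_frac3	dls_four_peaks	uv280_mg_ml	uv420_mg_ml
B1	IS		70	3.9e8	40	4.8e10	LP						25.1	13.8
B2	IS				10	1.8e10		411	0.01	0.63	0.27	TRUE	4.70
B3	SN			1.0e6	10	1.4e10		563	0.17	0.62	0.22		19.6	1.02
B4	SN			3.6e5		1.3e9		24	0.02	0.36	0.53	TRUE	0.87	0.01
B5	IS			6.6e6	50	1.8e11		1681	0.22	0.78			1.54	1.53
B8	IS			3.3e5		3.4e9						0.9	2.74
S1	IS						UDL						25
S6	IS			2.1e5			UDL						25
S9	IS					2.8e8						24
S11	IS				3
S12	IS						UDL						27
S13	IS				10
T1	IS			4.4e7		9.6e8		70				0.09
P1	IS			3.6e8							0.13
P2	IS			6.7e5							0.08
P3	IS			7.1e5		6.3e8	BA	17				1.25
P4	IS			3.6e5		4.0e8	LP	5.2				1.19
P11	IS			3.9e5		2.1e8	LP					0.16
P12	IS			3.8e4		3.1e8	LP					0.19
P16	IS			7.3e5		5.1e8	LP/BA					0.37
P21	SN			2.0e5		3.4e8	LP					0.19
P26	SN			7.4e4		2.4e8	LP/BA					0.88
LA		1000x	1000	1.3e9	5e4	9.7e13		117	0.05	0.95			370
LB		1000x	1000	6.3e8	2e4	9.9e13		131	0.27	0.73			340
LC		1000x	1000	1.7e9	2e5	1.5e14		170	0.01	0.67	0.32		400
LA		100x			2e5	1.1e14		961	0.01	0.99			355
LB		100x			2e5	7.8e13		973	0.04	0.96			322
LC		100x			2e5	1.1e14		1353	0.06	0.67	0.26		378
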