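effect	sum_sq	df	mean_sq	f_value	p_value	partial_eta_sq
Time-of-day	0.0837	2	0.04183	1.93	0.155	0.067
Time-of-day x cycle	0.5616	2	0.28081	12.97	0.001	0.325
Time-of-day x day_length	0.0917	2	0.04583	2.12	0.130	0.073
Residual (time-of-day)	1.1688	54	0.02164	NA	NA	NA
Day condition	0.1328	2	0.06640	7.37	0.001	0.214
Day condition x cycle	0.0793	2	0.03966	4.40	0.017	0.140
Day condition x day_length	0.2235	2	0.11176	12.41	0.001	0.315
Residual (day condition)	0.4864	54	0.00901	NA	NA	NA
Time-of-day x day condition	0.1101	4	0.02753	2.40	0.054	0.082
Time-of-day x day condition x cycle	0.3280	4	0.08200	7.16	0.001	0.210
Time-of-day x day condition x day_length	0.1574	4	0.03934	3.44	0.011	0.113
Residual (three-way)	1.2366	108	0.01145	NA	NA	NA
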