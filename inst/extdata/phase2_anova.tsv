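effect	sum_sq	df	mean_sq	f_value	p_value	partial_eta_sq
Time-of-day	0.15564	2	0.07782	29.22	0.001	0.880
Time-of-day x cycle	0.00558	2	0.00279	1.05	0.394	0.208
Residual (time-of-day)	0.02131	8	0.00266	NA	NA	NA
Day condition	0.07801	2	0.03900	83.80	0.001	0.954
Day condition x cycle	0.000309	2	0.000155	0.33	0.727	0.077
Residual (day condition)	0.00372	8	0.000465	NA	NA	NA
Time-of-day x day condition	0.15273	4	0.03818	16.75	0.001	0.807
Time-of-day x day condition x cycle	0.01102	4	0.00276	1.21	0.345	0.232
Residual (three-way)	0.03647	16	0.00228	NA	NA	NA
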