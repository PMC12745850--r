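effect	sum_sq	df	mean_sq	f_value	p_value	partial_eta_sq
Time-of-day	0.0439	2	0.02193	1.05	0.359	0.048
Time-of-day x cycle	0.1838	2	0.09188	4.39	0.019	0.173
Residual (time-of-day)	0.8784	42	0.02091	NA	NA	NA
Day condition	0.0801	2	0.04006	3.46	0.041	0.141
Day condition x cycle	0.1284	2	0.06419	5.54	0.007	0.209
Residual (day condition)	0.4867	42	0.01159	NA	NA	NA
Time-of-day x day condition	0.0230	4	0.00576	0.44	0.779	0.021
Time-of-day x day condition x cycle	0.1556	4	0.03889	2.98	0.024	0.124
Residual (three-way)	1.0972	84	0.01306	NA	NA	NA
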