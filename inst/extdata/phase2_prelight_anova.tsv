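effect	sum_sq	df	mean_sq	f_value	p_value	partial_eta_sq
Day condition	0.00352	2	0.00176	0.98	0.415	0.197
Day condition x cycle	0.00465	2	0.00233	1.30	0.324	0.245
Residual	0.01432	8	0.00179	NA	NA	NA
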