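effect	sum_sq	df	mean_sq	f_value	p_value	partial_eta_sq
Day condition	0.0263	2	0.01316	2.17	0.127	0.094
Day condition x cycle	0.0808	2	0.04040	6.67	0.003	0.241
Residual	0.2545	42	0.00606	NA	NA	NA
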