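condition	interval	n	mean	sem
Light1	pre-light	30	1.24	0.018
Light2	pre-light	30	1.28	0.021
Dark	pre-light	30	1.24	0.019
Light1	light-on	30	1.07	0.043
Light2	light-on	30	1.05	0.050
Dark	light-on	30	1.22	0.019
Light1	post-light	30	1.29	0.023
Light2	post-light	30	1.24	0.020
Dark	post-light	30	1.25	0.015
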