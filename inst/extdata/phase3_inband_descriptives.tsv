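condition	interval	n	mean	sem
Light1	pre-light	23	1.257	0.021
Light2	pre-light	23	1.301	0.021
Dark	pre-light	23	1.241	0.019
Light1	light-on	23	1.037	0.045
Light2	light-on	23	1.000	0.059
Dark	light-on	23	1.237	0.018
Light1	post-light	23	1.283	0.021
Light2	post-light	23	1.262	0.019
Dark	post-light	23	1.248	0.018
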