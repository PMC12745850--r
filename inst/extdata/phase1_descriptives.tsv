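condition	interval	n	mean	sem
Light1	pre-light	23	0.890	0.022
Light2	pre-light	23	0.898	0.017
Dark	pre-light	23	0.840	0.017
Light1	light-on	23	1.035	0.044
Light2	light-on	23	0.914	0.056
Dark	light-on	23	0.929	0.014
Light1	post-light	23	0.830	0.014
Light2	post-light	23	0.784	0.012
Dark	post-light	23	0.918	0.024
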