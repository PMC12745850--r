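condition	interval	n	mean	sem
Light1	pre-light	6	0.834	0.031
Light2	pre-light	6	0.863	0.016
Dark	pre-light	6	0.778	0.015
Light1	light-on	6	1.404	0.038
Light2	light-on	6	0.997	0.029
Dark	light-on	6	0.818	0.018
Light1	post-light	6	0.815	0.017
Light2	post-light	6	0.894	0.020
Dark	post-light	6	0.849	0.013
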