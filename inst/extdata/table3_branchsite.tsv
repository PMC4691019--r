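hypothesis	lnL	p0	p1	p2a	p2b	w0_bg	w0_fg	w1_bg	w1_fg	w2a_bg	w2a_fg	w2b_bg	w2b_fg	two_delta_lnl
alternative	-9212.750	0.36828	0.56715	0.02542	0.03915	0.17271	0.17271	1	1	0.17271	999	1	999	35.237
null	-9230.368	0.31965	0.45639	0.09225	0.13171	0.17495	0.17495	1	1	0.17495	1	1	1	NA
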