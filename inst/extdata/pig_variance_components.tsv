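trait	method	sigma_a2	sigma_e2	sigma_p2	h2	se_h2
AGE	PBLUP	59.24	69.29	128.53	0.46	0.01
AGE	ssGBLUP	66.74	67.31	134.04	0.50	0.01
ADG	PBLUP	1029.10	1248.80	2278.00	0.45	0.01
ADG	ssGBLUP	1163.50	1211.60	2375.00	0.49	0.01
BF	PBLUP	3.28	3.93	7.21	0.45	0.01
BF	ssGBLUP	3.70	3.81	7.51	0.49	0.01
EMA	PBLUP	1.93	6.60	8.52	0.22	0.01
EMA	ssGBLUP	2.01	6.62	8.63	0.23	0.01
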