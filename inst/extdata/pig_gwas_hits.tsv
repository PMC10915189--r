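trait	snp_id	chrom	bp	p_value
AGE	ALGA0006623	1	160347188	1.26E-15
AGE	ASGA0004992	1	160210902	8.97E-11
AGE	ASGA0005017	1	161540913	5.45E-09
AGE	ALGA0006690	1	162147201	6.19E-08
AGE	H3GA0003149	1	162192627	6.36E-08
AGE	ASGA0005021	1	161657225	1.13E-06
AGE	ALGA0112558	1	270826950	6.37E-06
AGE	MARC0037204	1	53549421	7.03E-06
AGE	ALGA0006707	1	162345362	2.34E-05
AGE	ALGA0012897	2	30421810	3.85E-06
AGE	DRGA0004818	4	59203000	1.58E-05
AGE	ALGA0105098	6	69291261	7.32E-11
AGE	H3GA0023150	7	113231192	1.30E-05
AGE	ALGA0047819	8	43646405	1.84E-07
AGE	ASGA0038525	8	32008618	8.44E-06
AGE	ALGA0113142	10	48069639	3.11E-05
AGE	ALGA0064467	12	7009388	2.27E-05
AGE	ALGA0080239	14	98332707	2.77E-05
AGE	ALGA0085484	15	54398519	2.28E-05
AGE	DRGA0016186	16	44656503	2.67E-07
ADG	ALGA0006623	1	160347188	1.60E-16
ADG	ASGA0004992	1	160210902	1.70E-11
ADG	ASGA0005017	1	161540913	3.45E-09
ADG	ALGA0006690	1	162147201	4.91E-08
ADG	H3GA0003149	1	162192627	5.04E-08
ADG	ASGA0005021	1	161657225	7.06E-07
ADG	ALGA0112558	1	270826950	2.61E-06
ADG	MARC0037204	1	53549421	8.37E-06
ADG	ALGA0006707	1	162345362	1.34E-05
ADG	ALGA0108601	1	160978649	2.34E-05
ADG	ALGA0006619	1	160247234	2.63E-05
ADG	ASGA0004994	1	160223900	3.27E-05
ADG	ALGA0006602	1	159538854	3.35E-05
ADG	ALGA0012897	2	30421810	1.08E-05
ADG	DRGA0004818	4	59203000	1.97E-05
ADG	ALGA0105098	6	69291261	4.60E-10
ADG	H3GA0023150	7	113231192	1.02E-05
ADG	ALGA0047819	8	43646405	1.16E-06
ADG	ALGA0113142	10	48069639	2.94E-05
ADG	ALGA0064467	12	7009388	5.21E-06
ADG	ALGA0080239	14	98332707	7.24E-06
ADG	ALGA0085484	15	54398519	4.08E-06
ADG	DRGA0016186	16	44656503	8.14E-08
BF	ALGA0012897	2	30421810	5.07E-10
BF	H3GA0013013	4	74199117	9.53E-06
BF	MARC0036560	5	66103958	1.56E-11
BF	H3GA0016584	5	66223267	3.44E-08
BF	ASGA0026705	5	89547600	2.14E-05
BF	H3GA0017689	6	22794083	1.77E-05
BF	H3GA0020739	7	29948363	3.25E-05
BF	ASGA0038525	8	32008618	1.68E-09
BF	ALGA0119031	9	36252818	8.07E-06
EMA	ASGA0005017	1	161540913	5.26E-08
EMA	ALGA0006623	1	160347188	1.69E-07
EMA	ALGA0006690	1	162147201	3.13E-07
EMA	H3GA0003149	1	162192627	3.59E-07
EMA	ALGA0007330	1	187227296	3.00E-06
EMA	ASGA0004992	1	160210902	7.09E-06
EMA	ASGA0005021	1	161657225	2.17E-05
EMA	ALGA0001723	1	22652735	2.35E-05
EMA	ALGA0025513	4	65186206	3.27E-06
EMA	ASGA0092589	6	155868122	1.89E-05
EMA	ASGA0032514	7	30234691	4.26E-06
EMA	ASGA0038525	8	32008618	2.25E-05
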