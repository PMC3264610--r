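species	group	cp_gc	mt_gc	mtpt_n	mtpt_bp	old_n	new_n	old_gc	new_gc
Chara	lower	26.19	40.9	11	915	11	0	54.54	NA
Marchantia	lower	28.81	42.41	16	1379	16	0	52.79	NA
Cycas	seed	39.45	46.92	40	17608	21	19	45.85	40.75
Triticum	seed	38.31	43.93	57	15089	54	3	44.63	34.49
Oryza	seed	38.99	43.85	71	34969	63	8	40.62	37.72
Sorghum	seed	38.49	43.73	49	33006	44	5	41.23	39.47
Zea	seed	38.46	43.93	41	24859	38	3	44.55	42.62
Arabidopsis	seed	36.29	44.77	30	5150	30	0	46.06	NA
Nicotiana	seed	37.85	44.96	43	11415	39	4	46.2	34.09
Vitis	seed	37.4	44.14	51	68925	33	18	40.52	34.08
Boea	seed	37.59	43.27	80	53440	45	35	41.59	35.32
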