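length	start1	orientation	start2	e_value_published	recombinant
1474	51709	P	232397	0.00E+00	TRUE
843	42273	P	108092	0.00E+00	TRUE
222	153742	F	405380	3.56E-118	TRUE
202	44767	F	395750	1.77E-111	FALSE
180	449174	F	504438	4.53E-93	FALSE
165	156474	P	272697	4.08E-84	FALSE
131	25864	P	291976	3.89E-66	FALSE
119	449235	F	504499	5.92E-59	FALSE
116	42870	P	246903	3.70E-57	FALSE
116	108222	F	246903	3.70E-57	FALSE
109	300367	F	308910	1.74E-55	FALSE
120	403184	P	496901	3.15E-55	FALSE
102	126580	P	462677	1.32E-44	FALSE
101	521	F	173834	5.13E-44	FALSE
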