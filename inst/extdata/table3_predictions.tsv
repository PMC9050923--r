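printed_id	compound_id	experimental_pgi50	predicted_pgi50	residual	test_set
14	14	5.04	5.33	-0.30	FALSE
16	16	4.88	4.90	-0.01	FALSE
17	17	5.40	5.26	0.15	FALSE
18	18	5.21	5.46	-0.25	FALSE
19	19	5.07	5.01	0.06	FALSE
36	36	4.85	5.04	-0.19	FALSE
56	56	6.77	6.31	0.46	FALSE
58	58	4.82	5.23	-0.41	TRUE
61	61	4.91	5.40	-0.49	FALSE
62	62	4.97	4.89	0.08	FALSE
70	70	6.49	5.85	0.64	FALSE
73	73	6.64	6.10	0.54	TRUE
74	74	5.88	6.16	-0.29	FALSE
77	77	6.02	6.03	-0.01	FALSE
78	78	4.88	5.78	-0.90	TRUE
71	81	4.85	5.29	-0.43	FALSE
95	95	4.89	5.16	-0.27	FALSE
99	99	4.94	4.28	0.66	TRUE
100	100	6.44	6.27	0.17	FALSE
101	101	7.22	6.55	0.67	TRUE
102	102	5.14	5.04	0.10	FALSE
103	103	5.38	5.29	0.09	FALSE
110	110	4.87	5.07	-0.20	FALSE
120	120	4.93	4.46	0.47	TRUE
121	121	4.86	4.82	0.04	FALSE
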