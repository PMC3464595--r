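name	count_perfect	count_imperfect	normalised_perfect	normalised_imperfect	log2fc	mode
miR319	21	171	0.96	7.05	2.88	Up
miR319a	121	1172	5.50	48.35	3.14	Up
miR319e	1	40	0.05	1.65	5.18	Up
miR160a	110	808	5.00	33.33	2.74	Up
miR393a	2	77	0.09	3.18	5.13	Up
miR394a	24	301	1.09	12.42	3.51	Up
miR395a	14	94	0.64	3.88	2.61	Up
miR6274	60	0	2.73	0.01	-8.09	Down
miR6268	178	66	8.10	2.72	-1.57	Down
miR6295	0	42	0.01	1.73	7.44	Up
miR319b	0	71	0.01	2.93	8.19	Up
miR171d	0	2097	0.01	86.51	13.08	Up
miR482c	30342	0	1380.12	0.01	-17.07	Down
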