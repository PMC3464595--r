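mirna_id	family_id	count_perfect	count_imperfect
miR156a	MIR156	45352	61361
miR156b	MIR156	26572	29886
miR156c	MIR156	145205	210543
miR156f	MIR156	118	188
miR156h	MIR156	0	4
miR156k	MIR156	25	46
miR157a	MIR156	735314	658343
miR157d	MIR156	8866	8738
miR159a	MIR159	18682	38726
miR319	MIR159	21	171
miR319a	MIR159	121	1172
miR319c	MIR159	6	7
miR319e	MIR159	1	40
miR319g	MIR159	0	5
miR160a	MIR160	110	808
miR162	MIR162	1	4
miR162a	MIR162	718	617
miR164a	MIR164	6256	4134
miR164f	MIR164	63	52
miR166	MIR166	60	85
miR166a	MIR166	222689	281639
miR166h	MIR166	1369	2013
miR167-3p	MIR167	810	691
miR167a	MIR167	151440	127360
miR167d	MIR167	52161	45113
miR167f	MIR167	61643	44482
miR168a	MIR168	64099	82261
miR169b	MIR169	510	538
miR169e	MIR169	10	6
miR169g	MIR169	11	1
miR169h	MIR169	18	10
miR171	MIR171	483	630
miR171b	MIR171	1578	1994
miR171d	MIR171	1	0
miR171f	MIR171	13	15
miR171b-3p	MIR171	2195	2831
miR171l	MIR171	4	9
miR172a	MIR172	13173	10393
miR172b	MIR172	5	0
miR172e	MIR172	181	181
miR172g	MIR172	123	102
miR2111a	MIR2111	0	5
miR390a	MIR390	18872	32445
miR390a-3p	MIR390	602	1207
miR393	MIR393	221	603
miR393a	MIR393	2	77
miR393b	MIR393	4	3
miR394a	MIR394	24	301
miR395a	MIR395	14	94
miR395b	MIR395	1	2
miR396a	MIR396	2046	3149
miR396b	MIR396	869	1194
miR398	MIR398	0	1
miR398a	MIR398	13	16
miR398b	MIR398	7	12
miR399a	MIR399	0	7
miR399f	MIR399	29	45
miR403	MIR403	325	510
miR408	MIR408	19	14
miR535a	MIR535	9743	12158
miR827a	MIR827	22512	21786
miR828a	MIR828	48	48
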