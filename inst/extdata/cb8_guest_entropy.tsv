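state	component	G1	G2	G3	G4	G5	G6	G7
unbound	S_GM_transvib	62	68	66	67	66	67	68
unbound	S_GM_rovib	59	67	61	62	65	68	64
unbound	S_G_pos	33	33	33	33	33	33	33
unbound	S_G_or	45	50	48	48	46	48	49
unbound	S_GUA_transvib	41	137	96	95	84	81	119
unbound	S_GUA_rovib	74	118	86	87	72	99	96
unbound	S_G_conf	20	29	0	2	16	7	17
unbound	S_WS_transvib	1144	1786	1458	1460	1335	1496	1663
unbound	S_WS_rovib	419	658	540	538	496	545	610
unbound	S_WS_or	72	126	97	278	254	277	311
unbound	N_WS	24.3	37.9	30.9	31.1	28.4	31.7	35.4
bound	S_GM_transvib	60	66	64	64	62	63	65
bound	S_GM_rovib	58	64	61	61	62	62	62
bound	S_G_pos	0	0	0	0	0	0	0
bound	S_G_or	23	23	23	23	23	23	23
bound	S_GUA_transvib	40	138	96	95	82	80	121
bound	S_GUA_rovib	72	116	86	84	70	99	95
bound	S_G_conf	12	22	0	1	10	6	1
bound	S_WB_transvib	1031	1395	1239	1242	1201	1248	1190
bound	S_WB_rovib	377	514	459	458	446	454	437
bound	S_WB_or	198	258	231	236	228	231	223
bound	N_WB	21.9	29.6	26.3	26.5	25.5	26.4	25.3
bound	S_WS_transvib	110	390	214	212	129	245	472
bound	S_WS_rovib	45	144	81	82	51	92	179
bound	S_WS_or	16	73	40	40	22	45	82
bound	N_WS	2.4	8.3	4.7	4.6	2.9	5.3	10.1
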