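component	H	H-G1	H-G2	H-G3	H-G4	H-G5	H-G6	H-G7
S_HM_transvib	70	70	69	69	69	68	69	69
S_HM_rovib	74	73	73	73	73	73	74	73
S_HUA_transvib	662	659	656	660	659	661	658	658
S_HUA_rovib	159	159	160	158	158	159	158	160
S_H_conf	0	0	0	0	0	0	0	0
S_WS_transvib	4079	3566	3440	3505	3526	3583	3555	3507
S_WS_rovib	1515	1310	1253	1275	1290	1312	1232	1270
S_WS_or	251	648	632	638	652	661	647	635
N_WS	87.4	76.4	73.7	75.2	75.4	76.9	76.2	75.3
S_WB_transvib	NA	516	644	573	563	491	525	569
S_WB_rovib	NA	190	238	211	208	181	194	210
S_WB_or	NA	123	153	136	134	117	125	135
N_WB	NA	11.0	13.7	12.2	12.0	10.5	11.2	12.1
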