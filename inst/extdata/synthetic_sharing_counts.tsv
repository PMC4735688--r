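sample	population	stratum	shared
L	NED	1	168
L	IBS	1	146
L	NED	2	257
L	IBS	2	214
L	NED	3	340
L	IBS	3	304
L	NED	4	387
L	IBS	4	338
L	NED	5	453
L	IBS	5	456
L	NED	6	486
L	IBS	6	460
L	NED	7	542
L	IBS	7	485
L	NED	8	551
L	IBS	8	542
L	NED	9	593
L	IBS	9	586
HI1	NED	1	151
HI1	IBS	1	126
HI1	NED	2	244
HI1	IBS	2	202
HI1	NED	3	269
HI1	IBS	3	215
HI1	NED	4	352
HI1	IBS	4	327
HI1	NED	5	406
HI1	IBS	5	370
HI1	NED	6	442
HI1	IBS	6	390
HI1	NED	7	507
HI1	IBS	7	444
HI1	NED	8	468
HI1	IBS	8	472
HI1	NED	9	487
HI1	IBS	9	494
HI2	NED	1	481
HI2	IBS	1	327
HI2	NED	2	626
HI2	IBS	2	513
HI2	NED	3	857
HI2	IBS	3	731
HI2	NED	4	971
HI2	IBS	4	887
HI2	NED	5	1039
HI2	IBS	5	974
HI2	NED	6	1181
HI2	IBS	6	1123
HI2	NED	7	1308
HI2	IBS	7	1273
HI2	NED	8	1406
HI2	IBS	8	1327
HI2	NED	9	1444
HI2	IBS	9	1460
O1	NED	1	367
O1	IBS	1	187
O1	NED	2	518
O1	IBS	2	307
O1	NED	3	626
O1	IBS	3	417
O1	NED	4	803
O1	IBS	4	536
O1	NED	5	820
O1	IBS	5	649
O1	NED	6	871
O1	IBS	6	796
O1	NED	7	962
O1	IBS	7	875
O1	NED	8	1040
O1	IBS	8	915
O1	NED	9	1063
O1	IBS	9	1007
O2	NED	1	315
O2	IBS	1	183
O2	NED	2	458
O2	IBS	2	325
O2	NED	3	550
O2	IBS	3	369
O2	NED	4	623
O2	IBS	4	448
O2	NED	5	711
O2	IBS	5	576
O2	NED	6	734
O2	IBS	6	648
O2	NED	7	834
O2	IBS	7	712
O2	NED	8	888
O2	IBS	8	755
O2	NED	9	975
O2	IBS	9	823
O3	NED	1	430
O3	IBS	1	303
O3	NED	2	648
O3	IBS	2	460
O3	NED	3	758
O3	IBS	3	538
O3	NED	4	918
O3	IBS	4	747
O3	NED	5	1038
O3	IBS	5	853
O3	NED	6	1124
O3	IBS	6	959
O3	NED	7	1135
O3	IBS	7	1157
O3	NED	8	1282
O3	IBS	8	1233
O3	NED	9	1420
O3	IBS	9	1299
O4	NED	1	347
O4	IBS	1	288
O4	NED	2	529
O4	IBS	2	439
O4	NED	3	661
O4	IBS	3	554
O4	NED	4	752
O4	IBS	4	654
O4	NED	5	890
O4	IBS	5	825
O4	NED	6	960
O4	IBS	6	895
O4	NED	7	1030
O4	IBS	7	989
O4	NED	8	1102
O4	IBS	8	1064
O4	NED	9	1278
O4	IBS	9	1135
HS1	NED	1	383
HS1	IBS	1	206
HS1	NED	2	542
HS1	IBS	2	327
HS1	NED	3	728
HS1	IBS	3	473
HS1	NED	4	789
HS1	IBS	4	569
HS1	NED	5	862
HS1	IBS	5	672
HS1	NED	6	926
HS1	IBS	6	840
HS1	NED	7	1040
HS1	IBS	7	909
HS1	NED	8	1032
HS1	IBS	8	1023
HS1	NED	9	1195
HS1	IBS	9	1047
HS2	NED	1	361
HS2	IBS	1	211
HS2	NED	2	519
HS2	IBS	2	329
HS2	NED	3	626
HS2	IBS	3	459
HS2	NED	4	729
HS2	IBS	4	559
HS2	NED	5	852
HS2	IBS	5	641
HS2	NED	6	899
HS2	IBS	6	751
HS2	NED	7	931
HS2	IBS	7	875
HS2	NED	8	1025
HS2	IBS	8	922
HS2	NED	9	1117
HS2	IBS	9	1021
HS3	NED	1	170
HS3	IBS	1	61
HS3	NED	2	211
HS3	IBS	2	141
HS3	NED	3	282
HS3	IBS	3	192
HS3	NED	4	332
HS3	IBS	4	231
HS3	NED	5	334
HS3	IBS	5	286
HS3	NED	6	360
HS3	IBS	6	291
HS3	NED	7	446
HS3	IBS	7	333
HS3	NED	8	415
HS3	IBS	8	363
HS3	NED	9	495
HS3	IBS	9	425
E1	NED	1	479
E1	IBS	1	261
E1	NED	2	726
E1	IBS	2	518
E1	NED	3	897
E1	IBS	3	642
E1	NED	4	993
E1	IBS	4	854
E1	NED	5	1053
E1	IBS	5	1014
E1	NED	6	1220
E1	IBS	6	1118
E1	NED	7	1336
E1	IBS	7	1257
E1	NED	8	1375
E1	IBS	8	1311
E1	NED	9	1582
E1	IBS	9	1518
E2	NED	1	453
E2	IBS	1	331
E2	NED	2	711
E2	IBS	2	506
E2	NED	3	808
E2	IBS	3	709
E2	NED	4	981
E2	IBS	4	841
E2	NED	5	1083
E2	IBS	5	1003
E2	NED	6	1168
E2	IBS	6	1121
E2	NED	7	1311
E2	IBS	7	1283
E2	NED	8	1485
E2	IBS	8	1327
E2	NED	9	1543
E2	IBS	9	1504
E3	NED	1	495
E3	IBS	1	323
E3	NED	2	713
E3	IBS	2	494
E3	NED	3	944
E3	IBS	3	667
E3	NED	4	1001
E3	IBS	4	852
E3	NED	5	1108
E3	IBS	5	1003
E3	NED	6	1219
E3	IBS	6	1152
E3	NED	7	1263
E3	IBS	7	1254
E3	NED	8	1469
E3	IBS	8	1301
E3	NED	9	1482
E3	IBS	9	1445
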