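protein_id	accession	chromosome	length	mol_weight	pI	instability_index	aliphatic_index	gravy
mrna00393	XP_011468749.1	LG7	320	35828.4	8.79	55.97	67.66	-0.853
mrna00517	XP_004309443.1	LG6	536	60527.7	6.67	67.1	68.51	-0.76
mrna01680	XP_004290316.1	LG2	585	64330.9	5.96	62.76	54.74	-0.909
mrna02177	XP_004289625.1	LG2	304	34175.6	5.05	71.42	66.38	-0.994
mrna02284	XP_004300452.2	LG5	148	17187.2	5.49	60.81	58.65	-0.943
mrna02614	XP_004292766.1	LG2	158	18178.4	8.9	68.19	67.34	-0.852
mrna03633	XP_004299018.1	LG4	711	76012.1	6.28	52.99	71.31	-0.488
mrna03778	XP_004297132.1	LG4	1106	122711.1	7.64	43.21	89.76	-0.056
mrna04187	XP_004304176.1	LG6	219	25024.5	5.63	64.63	65.89	-0.886
mrna04504	XP_004298330.2	LG4	585	64648.6	6.74	44.74	78.62	-0.458
mrna07554	XP_004289872.1	Unanchored	270	29591	6.01	33.29	57.48	-0.776
mrna07844	XP_011460972.1	LG3	324	36127.8	6.36	45.93	74.1	-0.667
mrna08154	XP_004290511.1	LG2	500	53629.2	6.25	54.88	69.92	-0.41
mrna08186	XP_004289896.1	LG2	425	46306.8	6.07	65.47	70.52	-0.723
mrna08484	XP_004291397.1	LG2	534	57868.1	5.95	60.87	61.22	-0.753
mrna08566	XP_004291338.1	LG2	216	23379.1	9.48	55.37	62.96	-0.634
mrna08757	XP_004291263.1	LG2	366	39534.3	5.49	46.89	64.56	-0.655
mrna09110	XP_004291101.1	LG2	487	52096.4	9.32	44.04	62.05	-0.64
mrna11666	XP_004291469.1	Unanchored	166	18034.9	9.56	68.79	70.6	-0.965
mrna11837	XP_004301547.1	LG5	277	29886.4	6.21	52.67	70.83	-0.739
mrna11979	XP_004303083.1	LG6	535	58896.3	8.66	51.21	88.77	-0.393
mrna13716	XP_011465109.1	LG5	889	96685.2	5.97	55.69	72.56	-0.57
mrna14220	XP_004307087.1	LG7	334	37188.7	7.83	55.28	81.92	-0.558
mrna14556	XP_004289074.1	LG1	227	25468.2	7.15	71.85	61.5	-0.899
mrna14942	XP_004287866.1	LG1	157	17845	4.93	44.46	79.49	-0.58
mrna15193	XP_004291844.1	LG2	171	19140.1	6.51	58.36	71.4	-0.794
mrna16561	XP_004302051.1	LG1	426	46739	5.18	63.18	57.98	-0.895
mrna17796	XP_004303124.1	LG6	329	37026.8	5.85	60.67	62.34	-1.004
mrna18282	XP_011467186.1	LG6	162	18593.9	7.08	60.44	84.81	-0.733
mrna18928	XP_004306702.1	LG7	427	45946.1	8.79	55.68	67.73	-0.725
mrna21344	XP_004307733.1	LG7	364	40093.2	5.91	59.84	59.84	-0.881
mrna21797	XP_004291604.1	Unanchored	543	60038	6.52	51.39	72.14	-0.545
mrna21832	XP_004289640.1	LG2	159	17974.9	6.29	66.22	66.98	-0.701
mrna21882	XP_011467317.1	LG6	631	70226	6.66	52.69	78.56	-0.428
mrna22776	XP_011462861.1	LG4	194	22165.9	5.34	53.68	54.74	-1.346
mrna23487	XP_004309615.1	LG4	445	48838.1	6.08	62.25	61.08	-0.783
mrna26148	XP_004301090.1	LG5	114	13507.3	9	46.47	94.04	-0.712
mrna27194	XP_011460752.1	LG3	848	93710.6	6.1	61.08	68.82	-0.549
mrna28103	XP_004296017.2	LG3	426	46283.3	6.35	59.02	56.92	-0.754
mrna28250	XP_004294799.1	LG3	432	46987.6	9.54	49.8	65.46	-0.663
mrna29159	XP_004300086.1	LG5	320	35003.2	4.73	59.96	80.22	-0.443
mrna29546	XP_004300611.1	Unanchored	734	80035.7	5.74	49.93	64.75	-0.662
mrna30252	XP_011466783.1	LG6	532	58072.2	7.49	61	67.74	-0.619
mrna30280	XP_011466768.1	LG6	437	47924.5	8.45	62.09	60.09	-0.778
mrna31321	XP_004301946.1	LG5	471	52672.4	8.48	47.98	67.94	-0.652
mrna31322	XP_011465538.1	LG5	351	39638.4	6.12	58.95	77.92	-0.572
mrna31621	XP_011466109.1	LG1	362	40736.2	6.35	43.26	79.59	-0.439
mrna32022	XP_011463954.1	LG5	262	28695.4	4.8	44.98	68.93	-0.842
mrna32024	XP_004298867.1	LG5	272	29939.3	4.97	47.36	82.1	-0.544
mrna32629	XP_004292529.1	LG2	336	37040.8	6.64	56.65	61.64	-0.838
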