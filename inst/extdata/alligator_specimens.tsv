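specimen_id	skull_length_mm	total_length_cm	sex	status	category
MOR OST 1646	28	102	?	?	juvenile
ROM R7964	32.02	22.4	F	?	juvenile
MOR OST 1645	33	14.7	?	?	juvenile
ROM R7966	34.7	28.3	M	?	juvenile
ROM R7965	38.83	24	M	?	juvenile
ROM R6251	42.99	31	?	?	juvenile
ROM R6252	43.1	29.8	?	?	juvenile
ROM R6253	43.33	19.8	?	?	juvenile
MOR OST 148	74	57.40 (e, M)	?	?	juvenile
ROM R8352	105.64	80.5	M	wild	juvenile
ROM R8349	107.93	81.75	F	wild	juvenile
ROM R8350	111.03	86.5	M	wild	juvenile
MOR OST 820	119	90.50 (e, M)	?	?	juvenile
MOR OST 1028	121	91.90 (e, M)	?	?	juvenile
ROM R8354	139.19	100	M	wild	juvenile
ROM R8355	147.97	113	M	wild	juvenile
ROM R8345	172.27	129	M	wild	subadult
ROM R4405	175.82	138.43	M	domestic	subadult
ROM R1698	195.74	?	?	?	subadult
ROM R8335	202.55	161.3	M	wild	subadult
ROM R4418	215.29	166.37	M	domestic	subadult
ROM R8332	226.94	176.5	M	wild	subadult
ROM R8334	244.72	198.1	F	wild	subadult
ROM R8322	247.44	191.8	F	wild	subadult
ROM R4420	247.93	182.88	M	domestic	subadult
MOR OST 1029	250	184.30 (e, M)	?	?	subadult
ROM R8347	252.43	191.3	F	wild	subadult
ROM R8323	254.86 (e)	204	F	wild	sexually_mature
ROM R4421	266.54	208.28	M	wild	sexually_mature
ROM R8331	277.00 (e)	215.9	F	wild	sexually_mature
ROM R8344	288.52	203.2	M	wild	sexually_mature
ROM R8336	330	243.8	M	wild	sexually_mature
MOR OST 156	340	247.40 (e, M)	?	?	sexually_mature
ROM R8342	343	247	F	wild	sexually_mature
ROM R4422	346	236.22	F	wild	sexually_mature
ROM R4416	350	242.97	F	domestic	sexually_mature
ROM R4401	357	269.88	F	domestic	sexually_mature
ROM R8343	370.00 (e)	264.1	F	wild	sexually_mature
ROM R8326	373	274.3	F	domestic	skeletally_mature
ROM R8327	375 (e)	276.9	F	domestic	skeletally_mature
MOR OST 155	380	275.30 (e)	M	wild	skeletally_mature
ROM R4415	405	287.02	M	domestic	skeletally_mature
ROM R8329	405	284.5	F	domestic	skeletally_mature
ROM R4411	445	330.2	M	domestic	skeletally_mature
MOR OST 795	464	333.30 (e)	?	?	skeletally_mature
ROM R8337		360.7	M	wild	skeletally_mature
ROM R8328		375.9	M	domestic	skeletally_mature
ROM R8324	580	383.6	M	wild	skeletally_mature
ROM R8333		381	M	domestic	skeletally_mature
ROM R51011	660	?	?	wild	?
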