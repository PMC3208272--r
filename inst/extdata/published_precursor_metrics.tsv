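mode	family	est_id	mature_seq	ref_species	ns	nn	arm	au_percent	amfe	mfei
sexual	miR156	ET5PU7E02HBOCM	UGACAGAAGAGAGAGAGCAC	Ath	U/A	75	5p	54.67	28.80	0.635
sexual	miR157	ET5PU7E02HBOCM	UUGACAGAAGAGAGAGAGCAC	Sbi	U/A	75	5p	54.67	28.80	0.635
sexual	miR159	ETM6Q5C04I3XE2	UUUGGUUUGAAGGAAGCUCUA	Ath	A/U,G/A	NA	NA	NA	NA	NA
sexual	miR160	ET5PU7E02JH8DI	UGCCUGGCUCCCUGUAUGCCA	Ath	NA	NA	NA	NA	NA	NA
sexual	miR161	ET5PU7E02IM9YA	UGAAAGUGACUACAUCGGGGU	Ath	NA	92	5p	55.43	24.67	0.554
sexual	miR164	ETM6Q5C04IAM5V	UGGAGAAGCAGGGCACGUAAA	Gar	NA	NA	NA	NA	NA	NA
sexual	miR166	ET5PU7E02JKLSI	CCGGACCAGGCUUCAUCCCAG	Pta	NA	NA	NA	NA	NA	NA
sexual	miR167	ETM6Q5C03GWWM2	UGAAGCUGCCAGCAUGAUCUA	Ath	NA	100	5p	60.00	48.20	1.201
sexual	miR170	ETM6Q5C03GVN0G	UGAUUGAGCCGCGCCAAUAUC	Ath	NA	NA	NA	NA	NA	NA
sexual	miR172	ET5PU7E02GZHSB	AGAAUCCUGAUGAUGCUGCAU	Ath	U/C	NA	NA	NA	NA	NA
sexual	miR319	ETM6Q5C03FYJ8Y	UUGGAAUGAAGGGAGCUCCAC	Ath	A/C,U/A,U/C	NA	NA	NA	NA	NA
sexual	miR394	ET5PU7E02IYKJ5	UUGGCAUUCUGUCCACCUCC	Ath	NA	116	5p	57.76	46.46	1.100
sexual	miR395	ETM6Q5C03FTE98	AUGAAGAGUUUGGAGGAACUC	Osa	U/A	NA	NA	NA	NA	NA
sexual	miR396	ET5PU7E02GM4DS	UCCACAGGCUUUCUUGAACGG	Ghr	NA	143	5p	41.96	38.37	0.661
sexual	miR398	ETM6Q5C04IDRCB	UGUGAUCUCAGGUAACCCCUU	Ath	U/A,C/A	NA	NA	NA	NA	NA
sexual	miR399	ET5PU7E02FZ073	UGCCAAAGGAGAUAUGCCCUA	Ath	U/A,G/A	NA	NA	NA	NA	NA
sexual	miR400	ET5PU7E02JJRIA	UAUGAGAGUAUUAUAUGUCAC	Ath	A/U	76	3p	60.53	15.79	0.400
sexual	miR403	ET5PU7E02I3RXE	UUAGAUUCACGCACAAACUCC	Ath	G/C	75	5p	57.33	24.93	0.584
sexual	miR408	ETM6Q5C04JX15C	AUGCACUGCCUCUUCCCUGGC	Ath	NA	148	3p	58.78	33.58	0.815
sexual	miR414	ET5PU7E02IZWR4	UCAUCAUCAUCAUCAUCGUCG	Ath	U/A,A/G	170	5p	51.18	29.29	0.600
sexual	miR414	ET5PU7E02GNU3F	NA	Ath	U/A	221	3p	51.01	23.62	0.482
sexual	miR414	ET5PU7E02I14IE	NA	Ath	U/A	233	3p	56.65	24.64	0.568
sexual	miR415	ETM6Q5C03FIL8C	GACAGAGAAGAAACAGAACAU	Ath	A/G,C/A	NA	NA	NA	NA	NA
sexual	miR444	ETM6Q5C04IXD3L	UUGCUGCCUCAAGCUCCCGGC	Zma	U/C,U/G	NA	NA	NA	NA	NA
sexual	miR482	ET5PU7E02HNZGI	UCUUCCCUACACCGCCCAUAC	Gso	U/G	NA	NA	NA	NA	NA
sexual	miR529	ET5PU7E02HC551	GCUCUUCCCUCUCUCUUCUUC	Osa	C/G,G/C,A/U	NA	NA	NA	NA	NA
sexual	miR824	ETM6Q5C04ISA8K	UAGACCAUUUGUGAGAAGAGA	Ath	G/A	NA	NA	NA	NA	NA
sexual	miR835	ETM6Q5C04JNEVJ	UUUUUCCAUAUGUUCUUUAUC	Ath	C/U,G/C	NA	NA	NA	NA	NA
sexual	miR838	ETM6Q5C03FOEE6	UUUUCUUCUACUUCUUCCCCA	Ath	G/C,A/C	NA	NA	NA	NA	NA
sexual	miR841	ETM6Q5C03HCEIS	UACGACCCACUGGAAACUGAA	Ath	G/C,U/G	NA	NA	NA	NA	NA
sexual	miR845	ET5PU7E02F58WO	UAGCUCUGAUACCAAAUGAUA	Vvi	U/A	NA	NA	NA	NA	NA
sexual	miR846	ETM6Q5C03FVWRY	UUGAAUUGGAGUGCUUGCAUU	Ath	A/G,A/C	NA	NA	NA	NA	NA
sexual	miR852	ETM6Q5C03G2GJO	AAGAUAAGCGCCUUAGGUCUG	Ath	U/G	89	5p	62.92	38.31	1.033
sexual	miR854	ETM6Q5C04JC8OP	GAUGAGGAGAAGGAGGAGGAG	Ath	U/G,G/A	NA	NA	NA	NA	NA
sexual	miR859	ET5PU7E02GYEM5	UCUCUCUGUUGUGAAAUCAAA	Ath	G/A	NA	NA	NA	NA	NA
sexual	miR860	ETM6Q5C03G8ZLD	UCAGUAGCUUGGACUAUGUAU	Ath	A/G,A/C	NA	NA	NA	NA	NA
sexual	miR861	ET5PU7E02IMVAL	CCUUGGAGAAAUAUGCUUCAA	Ath	G/U	NA	NA	NA	NA	NA
sexual	miR865	ETM6Q5C04JQMWD	UUUCUCCUCAAAUUUCUCCAA	Ath	U/C,A/C	NA	NA	NA	NA	NA
sexual	miR869	ET5PU7E02JV51F	CAUGGUUCAAUGCAGGUGCUA	Gma	U/A,U/C	NA	NA	NA	NA	NA
apomictic	miR156	ETM6Q5C01AY29E	UGACAGAAGAGAGAGAGCAC	Ath	U/A	66	5p	53.03	30.00	0.639
apomictic	miR156	ET5PU7E01BE5BP	UGACAGAAGAGAGAGAGCAC	Ath	U/A	105	5p	52.38	25.24	0.530
apomictic	miR157	ET5PU7E01A5S8V	UUGACAGAAGAGAGAGGGCAC	Ath	A/G	119	5p	57.98	32.10	0.764
apomictic	miR159	ETM6Q5C02EBWUA	UUUGGACUGAAGGGAGCUCCU	Ath	U/C	NA	NA	NA	NA	NA
apomictic	miR160	ET5PU7E01AQT2A	UGCCUGGCUCCCUGUAUGCCA	Ath	NA	110	5p	58.18	42.10	1.007
apomictic	miR161	ETM6Q5C01AMWRE	UCAAUGCAUUGAAAGUAACUA	Ath	G/A	NA	NA	NA	NA	NA
apomictic	miR162	ETM6Q5C01AZ87O	UCGAUAAACCUCUGCAUCCAG	Ptc	NA	84	3p	55.95	48.45	1.100
apomictic	miR166	ET5PU7E01CXVM2	CCGGACCAGGCUUCAUCCCCC	Pta	A/C,G/C	NA	NA	NA	NA	NA
apomictic	miR167	ETM6Q5C01CA126	UGAAGCUGCCAGCAUGAUCUA	Ath	NA	100	5p	60.00	48.20	1.205
apomictic	miR169	ETM6Q5C01B8RXC	UGAGCCAAGGAUGAUUUGCCU	Ath	C/U,G/U	NA	NA	NA	NA	NA
apomictic	miR170	ET5PU7E01EN973	UGAUUGAGCCGCGCCAAUAUC	Ath	NA	121	3p	51.24	40.50	0.831
apomictic	miR172	ET5PU7E01CV6Q5	AGAAUCUUGAUGAUGCUGCAU	Ath	NA	142	3p	49.30	22.39	0.442
apomictic	miR319	ETM6Q5C02EBWUA	UUGGACUGAAGGGAGCUCCUU	Ath	NA	184	3p	57.61	45.20	1.066
apomictic	miR394	ET5PU7E01CBSOI	UUGGCAUUCUGUCAACCUCC	Ath	C/A	126	3p	57.94	19.13	0.455
apomictic	miR395	ETM6Q5C02DVQZ4	AUGAAGAGUUUGGAGGAACUC	Osa	U/A	NA	NA	NA	NA	NA
apomictic	miR396	ETM6Q5C02DSTK1	UCCACAGGCUUUCUUGAACGG	Ghr	NA	NA	NA	NA	NA	NA
apomictic	miR398	ET5PU7E01B8LVW	UGUGUUCUCAGGUCACCCCUU	Ath	NA	NA	NA	NA	NA	NA
apomictic	miR400	ET5PU7E01AVMRY	UAUGAGAGUAUUAUAGGUCAC	Ath	A/G	NA	NA	NA	NA	NA
apomictic	miR408	ET5PU7E01EE6T6	AUGCACUGCCUCUUCCCUGGC	Ath	NA	89	3p	52.81	39.55	0.838
apomictic	miR414	ET5PU7E01DL36L	UCAUCAUCAUCAUCAUCGUCU	Ath	U/A,A/U	208	3p	57.69	16.92	0.400
apomictic	miR414	ET5PU7E01BXM22	UCAUCAUCAUCAUCAUCGUCG	Ath	U/A,A/G	170	5p	50.88	29.29	0.603
apomictic	miR414	ET5PU7E01D5L0P	UCAUCGUCAUCAUCAUCGUCA	Ath	U/G	104	5p	63.46	29.33	0.803
apomictic	miR415	ETM6Q5C01A4TW0	GACAGAGAAGAAACAGAACAU	Ath	A/G,C/A	135	5p	56.30	24.96	0.571
apomictic	miR472	ETM6Q5C01B63E7	UUUUGCCUACUCCACCCAUACC	Ath	U/G,G/A	NA	NA	NA	NA	NA
apomictic	miR529	ETM6Q5C02D6DWQ	CUCUUCCCUCUCUCUUCUUC	Osa	G/C,A/U	NA	NA	NA	NA	NA
apomictic	miR776	ET5PU7E01CU8R6	UCUAAUUCUUCUAUUGAUAUU	Ath	G/U,G/A	NA	NA	NA	NA	NA
apomictic	miR820	ET5PU7E01CXV4L	UCGUACUCGUGGAUGGACCAG	Osa	G/U,C/A	NA	NA	NA	NA	NA
apomictic	miR824	ETM6Q5C01BUUMV	UAGACCAUUUGUGAGAAGAGA	Ath	G/A	NA	NA	NA	NA	NA
apomictic	miR835	ET5PU7E01BKF2J	UUUUUCCAUAUGUUCUUUAUC	Ath	C/U,G/C	NA	NA	NA	NA	NA
apomictic	miR840	ETM6Q5C02C26W5	ACACUGAAGGAGCUGAACUAAU	Ath	C/G,A/G,C/U	NA	NA	NA	NA	NA
apomictic	miR841	ETM6Q5C01B0IVV	UACGACCCACUGGAAACUGAA	Ath	G/C,U/G	NA	NA	NA	NA	NA
apomictic	miR846	ETM6Q5C02D2FL9	UUGAAUUGGAGUGCUUGCAUU	Ath	A/G,A/C	NA	NA	NA	NA	NA
apomictic	miR854	ETM6Q5C01A9E26	GAUGAUGAUAGUGAGGAGGAG	Ath	G/U,G/U	NA	NA	NA	NA	NA
apomictic	miR857	ETM6Q5C01AWYYJ	UUAUGUAUGUUGAAUGUGUAU	Ath	U/A,G/U	NA	NA	NA	NA	NA
apomictic	miR859	ET5PU7E01E1HDI	UCUCUCUGUUGUGAAAUCAAA	Ath	G/A	NA	NA	NA	NA	NA
apomictic	miR860	ETM6Q5C02DJ9H7	UCAGUAGCUUGGACUAUGUAU	Ath	A/G,A/C	NA	NA	NA	NA	NA
apomictic	miR861	ET5PU7E01A7VRK	CCUUGGAGAAAUGUGCUUCAA	Ath	A/G,G/U	233	5p	51.93	31.93	0.664
apomictic	miR865	ETM6Q5C02DTC6W	UUUCUCCUCAAAUUUCUCCAA	Ath	U/C,A/C	NA	NA	NA	NA	NA
apomictic	miR869	ET5PU7E01A48FH	CAUGGUUCAAUGCAGGUGUUA	Gma	U/A	NA	NA	NA	NA	NA
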