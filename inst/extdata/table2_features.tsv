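gene_name	ccdb_id	ncbi_gene_id	locus	exons	mrna_bp	length_aa	mw_kda	pi	tmh	loc_mploc	loc_wolfpsort
CmPIP1;1	MELO3C025164.2	103501427	chr10: 9455124 .. 9456876 (−)	3	1202	292	31.47	7.67	5	plas	plas
CmPIP1;2	MELO3C005685.2	103482758	chr09: 23466873 .. 23469204 (+)	4	1275	286	30.71	9.13	6	plas	plas
CmPIP2;1	MELO3C014240.2	103491188	chr05: 4877174 .. 4878743 (+)	4	1172	284	29.86	7.71	7	plas	plas
CmPIP2;2	MELO3C014241.2	103491189	chr05: 4867151 .. 4869395 (−)	4	1239	284	30.21	8.78	6	plas	plas
CmPIP2;3	MELO3C014239.2	107990277	chr05: 4880993 .. 4882676 (+)	4	1245	284	29.89	8.22	6	plas	plas
CmPIP2;4	MELO3C025772.2	103501948	chr11: 28209027 .. 28210647 (−)	3	1381	283	30.36	7.63	6	plas	plas
CmPIP2;5	MELO3C019794.2	103496419	chr03: 23650515 .. 23655241 (+)	4	1390	276	29.37	9.56	6	plas	plas
CmPIP2;6	MELO3C014238.2	103491187	chr05: 4886375 .. 4887984 (+)	4	1178	279	30.02	8.58	6	plas	plas
CmPIP2;7	MELO3C012429.2	103489467	chr10: 537492 .. 541727 (−)	4	1116	287	31.24	9.41	6	plas	plas
CmPIP2;8	MELO3C009337.2	103486477	chr04: 32797579 .. 32799526 (+)	3	1490	289	31.03	9.10	6	plas	plas
CmPIP2;9	MELO3C014244.2	103491191	chr05: 4857028 .. 4859643 (−)	4	1308	278	29.40	8.58	6	plas	plas
CmPIP2;10	MELO3C013347.2	103490279	chr01: 16804141 .. 16806721 (−)	4	1199	280	29.91	9.24	6	plas	plas
CmTIP1;1	MELO3C024483.2	103500838	chr08: 10141935 .. 10143868 (+)	2	975	250	25.67	5.64	7	tono	plas
CmTIP1;2	MELO3C009377.2	103486517	chr04: 32517961 .. 32520018 (+)	2	988	253	26.34	6.03	7	tono	cyto, tono
CmTIP1;3	MELO3C025466.2	103501648	chr09: 5838747 .. 5839429 (−)	3	1145	253	26.55	5.53	6	tono	cyto, plas, tono
CmTIP2;1	MELO3C024263.2	103500601	chr01: 35574300 .. 35575883 (+)	3	1232	248	25.43	5.66	6	tono	tono
CmTIP2;2	MELO3C005526.2	103482603	chr09: 22169680 .. 22172778 (−)	3	1150	250	25.09	5.39	6	tono	tono
CmTIP3;1	MELO3C002183.2	103482730	chr12: 25767948 .. 25770390 (−)	3	1137	284	30.08	7.17	5	tono	mito
CmTIP4;1	MELO3C011146.2	103488186	chr03: 28321088 .. 28322961 (+)	3	1087	247	25.70	5.91	7	tono	tono
CmTIP5;1	MELO3C005441.2	103504693	chr09: 21620302 .. 21621635 (−)	3	957	260	26.86	8.31	6	plas	chlo
CmNIP1;1	MELO3C007188.2	103484424	chr08: 1361212 .. 1363293 (−)	5	1326	276	29.54	9.48	6	plas	plas
CmNIP2;1	MELO3C009870.2	103487002	chr04: 28593871 .. 28598610 (−)	5	1360	287	30.41	9.15	6	plas	plas, tono
CmNIP2;2	MELO3C009871.2	103487003	chr04: 28560873 .. 28564531 (−)	5	1232	261	27.52	6.29	6	plas	plas
CmNIP4;1	MELO3C020281.2	103496839	chr06: 14916752 .. 14920413 (−)	5	1021	269	28.81	7.64	5	plas	tono
CmNIP5;1	MELO3C005818.2	103482897	chr09: 24541790 .. 24547172 (−)	4	1794	298	30.83	8.64	5	plas	plas
CmNIP5;2	MELO3C005817.2	103482896	chr09: 24536633 .. 24540050 (−)	5	1044	250	26.19	8.62	6	plas	tono
CmNIP6;1	MELO3C017831.2	103494651	chr07: 27500120 .. 27503882 (+)	5	2218	304	31.66	7.64	6	plas	tono
CmNIP7;1	MELO3C006559.2	103483738	chr06: 4173677 .. 4176268 (−)	5	1123	268	28.52	6.38	6	plas	plas
CmSIP1;1	MELO3C008793.2	103485971	chr08: 26514604 .. 26519163 (+)	3	1287	243	25.58	9.55	6	plas	tono
CmSIP2;1	MELO3C009719.2	103486855	chr04: 29912868 .. 29916655 (−)	3	1275	316	34.88	9.72	6	plas	plas
CmXIP1;1	MELO3C020774.2	103497290	chr11: 4268119 .. 4268934 (+)	2	1148	316	34.21	6.88	7	plas	plas
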