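gene_name	forward	reverse	product_bp	dg_primer_f	dg_primer_r	dg_self_f	dg_self_r	dg_hetero	efficiency_pct	tm_melting_c	ta_annealing_c	dilution
CmRAN	TGCACCCTTTGGACTTCTTC	GATGTAGTAGCCATCCCGTAAAC	104	-	-	-	-	-	98.7	-	-	-
CmPIP1;1	GCTTCTTCAATCAATCACAGC	ACCATTACATAGCTTCATAGCC	181	−37.26	−38.53	−4.74	−6.34	−4.74	99.7	75.81	60	1:10
CmPIP1;2	CATTCTTCCCCAAAAGCAAA	AGTTTTCAGAAAGGCAGCCA	179	−39.64	−38.89	−3.54	−6.21	−5.49	98.81	76.17	60	1:10
CmPIP2;1	TTAAGCCTAATAGTTGTGTGC	AAAAGAGAGCAAAAACCACG	147	−36.17	−39.91	−4.85	−3.61	−5.09	100.36	75.16	60	1:2
CmPIP2;2	GGATCTAAAATGTGTGATTAGG	ATAAAACCTTCAAAATATGTGC	158	−36.73	−37.88	−4.62	−3.91	−4.67	100.15	73.91	57	1:10
CmPIP2;3	ATCTCTAACATCCATCACTCC	TAGTTAGCTTGTGGTGGTCG	94	−34.68	−36.3	−1.47	−6.34	−5.85	99.98	76.96	60	1:5
CmPIP2;4	CTCTCGTCTGCTTTGGTCC	ATACATAGGATGAGAATGAGC	158	−36.06	−34.27	−3.61	−3.43	−4.75	99.13	75.14	60	1:5
CmPIP2;5	TTCCTTTTGCTATTGGAATGG	TTGCCTGTTACATTACTAGG	89	−42.08	−36.1	−6.59	−4.67	−5.37	100.32	71.69	57	1:5
CmPIP2;6	TCTGCTCTATAAATCTTATCCC	TAACACACTTCATTAGTTCAGC	144	−37.07	−35.44	−4.38	−3.29	−4.74	99.43	74.25	57	1:2
CmPIP2;7	CCATTCCATAAGCAAAAGACT	GAACATTAGTAAGCCAAGTGG	177	−38.06	−36.71	−3.14	−5.02	−5.02	96.27	72.00	60	1:2
CmPIP2;8	ACAAAACCAAAGAAGTGTTCG	GCAGGATCTCAGTGAATGTG	158	−37.87	−34.65	−3.61	−4.62	−3.52	99.72	76.51	60	1:5
CmPIP2;9	CTTCTTCCTTACACTTCATGC	TTACCCAATTACAAAAGATTGC	119	−36.09	−39.48	−5.38	−5.37	−5.12	97.43	73.48	60	1:2
CmPIP2;10	AAGAAGATGATGGTAGAAGTGG	CATTCAAAGACAATCCCTTCC	120	−37.12	−38.58	−1.47	−3.54	−5.12	99.95	73.21	60	1:10
CmTIP1;1	CGTCAACTTCTTTGTTCTACGT	CAATTTAATACGACATCAAAATGG	90	−38.04	−41.76	−6.30	−5.36	−5.84	95.41	73.29	60	1:10
CmTIP1;2	TCAACCACCACCACCACC	GACACGACCAAACCCATCC	129	−34.34	−37.21	Non	−3.61	−1.57	99.44	75.19	60	1:5
CmTIP1;3	TCTTGACTTTATTCAGAGACC	ATTCTCTTCCTGATTCTTAGC	105	−34.14	−35.72	−3.53	−3.14	−6.35	99.90	72.66	57	1:2
CmTIP2;1	TCCCTTTGTAATAAGAGGAGG	AAGAAGAGAATCCAATGAACC	133	−37.87	−36.73	−4.67	−1.95	−4.64	99.64	73.77	60	1:10
CmTIP2;2	GTGTAAAAAATGAAACCAAAACG	TTGAGGGAAAACCGAAGAAGG	150	−41.36	−41.95	−1.95	−3.61	−3.90	99.82	77.43	60	1:2
CmTIP3;1	TTTCTGCTCTATATGTTGTAGG	CTGTATGACATTTATTACCTTC	144	−35.96	−34.39	−3.91	−3.43	−4.77	100.3	75.69	57	1:10
CmTIP4;1	GTCATCATACTTACCATTTGC	ACTACAAGAAACTGGAAAGG	104	−34.98	−34.30	−3.14	−1.95	−5.02	98.37	74.58	60	1:2
CmTIP5;1	TTTAAGCGTTGGTTTTGTGC	GATAAAAATTCATGTTAGATACAC	97	−39.02	−36.66	−4.85	−5.38	−5.83	99.10	72.01	60	1:2
CmNIP1;1	CCTTACTTCACATGAAACTAGG	CAGCCATCAAGAAGTTTGG	99	−36.74	−35.63	−5.47	−5.02	−6.83	100.3	73.11	60	1:5
CmNIP2;1	ATAGTTTGAGTGTTTTAATGAGC	GGCTACTTCTGATACATTGC	124	−37.51	−34.6	−4.85	−3.14	−5.37	100.3	71.99	60	1:10
CmNIP2;2	GAGAAGAATGAATCTGAAATAGG	GAAAAGAAGAACCAATTTTATGG	115	−37.93	−40.72	−3.17	−5.83	−5.36	99.05	70.03	60	1:5
CmNIP4;1	AAAGGAAGAACATAAACGATAAC	ATTGAGTCTCAGAAAGAAAGG	86	−39.06	−35.38	−3.61	−5.13	−3.9	99.21	72.27	60	1:5
CmNIP5;1	AGAATAAAGTTGAGAAGAAAAGG	GGCAAGTAGAAACAATATAGCA	95	−38.65	−37.87	−1.94	−3.91	−3.9	98.87	73.47	60	1:10
CmNIP5;2	TGATAATGATAGTGGTCGTTG	TTGACATGAAAGTAAAAGGTCG	75	−35.08	−38.59	−3.61	−5.38	−3.61	100.2	72.54	60	1:5
CmNIP6;1	CCCAGAGAACACTTTGAACC	ATACACAATGACCAATACTTGC	137	−36.39	−36.7	−1.95	−3.90	−3.9	100.2	75.56	60	1:5
CmNIP7;1	CCCTCTATATTTCCAGTTGC	AAGTAAGGTTTAATTTGATTACCG	132	−36.25	−41.89	−3.91	−5.36	−4.67	100.7	72.46	60	1:2
CmSIP1;1	GCAGTTATGTTTAGTTTGATTC	CTAATGTCCAAAGTCTATAAGC	92	−35.91	−35.95	−3.14	−3.40	−5.84	100.5	71.54	60	1:2
CmSIP2;1	CTCTTAATGATTCCAATGTAGTG	TGACGATGTTGTCGGATTCC	101	−37.21	−37.96	−4.85	−5.19	−4.64	98.77	76.71	60	1:2
CmXIP1;1	TCTTCCTCTTTTCTCTCAAGG	GCAGTCGCTACTAATTCTGTC	101	−36.86	−36.23	−4.67	−5.36	−1.95	NM	71.82	60	1:2
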