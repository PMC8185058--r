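site_id	coordinates	region	peatland_type	pH	TN	NH4	NO3	TP	PO4	OM	DOC	SO4	Fe2	Fe3	TFe	TMn	ORP
QL	47°46′N, 132°54′E	SJ	NA	7.12	2.77	1.70	0.11	0.08	0.03	126.40	13.66	10.41	0.51	0.85	1.36	3.84	120.33
HH1	47°43′N, 133°35′E	SJ	NA	6.20	2.04	0.04	1.04	0.05	0.01	243.73	41.71	0.95	1.01	2.71	3.72	3.58	111.00
HH2	47°47′N, 133°38′E	SJ	NA	6.20	2.98	0.02	1.02	0.15	0.05	392.33	63.08	1.30	1.18	0.46	1.63	5.48	118.00
BL	47°32′N, 133°54′E	SJ	NA	7.08	2.44	0.05	0.97	0.13	0.06	244.37	19.14	0.93	1.02	1.16	2.51	2.27	145.67
SJZ	47°32′N, 133°54′E	SJ	NA	6.34	2.62	0.04	1.03	0.08	0.03	279.00	59.03	0.79	1.03	1.33	2.36	4.80	124.67
JC1	42°21′N, 126°22′E	CB	NA	6.19	2.22	0.07	0.66	0.08	0.03	386.87	96.39	2.00	1.84	11.52	13.36	6.42	81.67
JC2	42°21′N, 126°22′E	CB	NA	6.17	2.37	0.07	0.86	0.07	0.02	405.30	78.87	2.03	1.91	8.58	10.49	8.71	83.00
JC3	42°21′N, 126°22′E	CB	NA	6.29	1.83	0.06	0.45	0.07	0.02	365.00	105.35	2.56	1.72	3.96	5.68	4.22	111.00
JC4	42°21′N, 126°22′E	CB	NA	6.05	2.21	0.06	0.33	0.10	0.02	400.93	34.92	2.30	2.10	7.73	9.83	12.14	93.33
WY1	48°34′N, 129°27′E	LK	NA	5.63	1.39	0.01	0.07	0.24	0.13	627.00	133.13	2.78	3.76	7.64	11.39	3.80	98.00
WY2	48°34′N, 129°27′E	LK	NA	5.17	2.18	0.03	0.18	0.26	0.12	938.13	163.20	0.98	3.84	5.29	9.13	15.63	156.33
WY3	48°33′N, 129°28′E	LK	NA	5.06	1.86	0.04	0.22	0.17	0.04	704.67	159.47	1.75	3.34	1.89	5.23	12.96	204.67
WY4	48°33′N, 129°28′E	LK	NA	5.29	1.28	0.01	0.07	0.08	0.01	510.20	61.42	1.24	1.49	1.21	2.71	16.84	106.00
TB2	48°25′N, 129°08′E	LK	NA	6.07	0.96	0.01	0.08	0.12	0.05	321.50	58.34	1.22	2.27	1.59	3.86	19.91	120.33
JS	51°08′N, 124°10′E	GK	NA	6.14	1.12	0.04	0.16	0.07	0.01	222.67	74.82	3.51	2.74	3.04	5.78	4.03	75.33
TQ1	52°57′N, 122°52′E	GK	NA	5.97	1.52	0.01	0.11	0.08	0.01	532.90	65.39	0.76	1.27	0.54	1.81	16.78	120.67
TQ2	52°57′N, 122°52′E	GK	NA	6.02	1.17	0.02	0.07	0.33	0.01	453.87	66.00	0.96	1.34	1.42	2.76	6.13	176.33
HT	51°37′N, 123°59′E	GK	NA	5.01	1.41	0.04	0.31	0.12	0.03	437.03	93.94	1.16	1.39	0.44	1.83	4.03	229.33
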