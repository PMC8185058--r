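site_id	coordinates	region	peatland_type	pH	TN	NH4	NO3	TP	PO4	OM	DOC	TS	SO4	Fe2	Fe3	TFe	TMn
QL	47°46′N, 132°54′E	SJ	NA	5.56	15.38	27.83	29.15	1.95	23.13	34.27	2.58	1.40	234.67	10.65	0.32	21.48	229.19
HH2	47°47′N, 133°38′E	SJ	NA	5.29	28.79	28.35	4.06	1.07	4.79	72.32	2.41	1.41	71.23	3.43	0.14	5.96	331.72
BL	47°32′N, 133°54′E	SJ	NA	5.59	21.27	37.27	34.53	1.03	15.08	43.29	2.75	1.44	91.37	5.46	0.33	13.12	231.59
JC1	42°21′N, 126°22′E	CB	NA	5.59	21.08	46.48	6.45	0.74	2.61	65.68	2.05	1.48	72.73	5.70	0.31	9.37	185.76
JC2	42°21′N, 126°22′E	CB	NA	5.15	19.98	55.14	4.63	0.70	2.72	65.77	3.00	1.67	70.68	4.12	0.50	8.46	219.02
JC3	42°21′N, 126°22′E	CB	NA	5.23	18.71	60.58	4.10	0.75	2.67	60.83	3.10	1.42	123.43	3.92	0.27	9.17	166.78
JC4	42°21′N, 126°22′E	CB	NA	5.20	19.89	40.95	5.33	0.80	2.35	67.55	2.13	1.47	87.42	4.73	0.48	7.60	126.36
WY1	48°34′N, 129°27′E	LK	NA	4.95	13.84	26.14	4.63	1.39	14.94	45.53	2.68	1.46	96.37	9.76	0.51	18.56	309.35
WY2	48°34′N, 129°27′E	LK	NA	4.83	14.63	21.90	5.31	1.25	9.78	60.04	3.34	1.63	117.55	6.95	0.38	11.13	261.21
WY3	48°33′N, 129°28′E	LK	NA	4.80	9.48	39.72	6.23	0.87	5.26	64.86	4.00	1.70	99.10	5.81	1.52	9.88	319.82
TB1	48°25′N, 129°08′E	LK	NA	4.48	13.08	21.29	3.74	1.23	5.47	57.37	4.22	1.73	76.76	3.27	7.31	18.39	228.58
TB2	48°25′N, 129°08′E	LK	NA	4.84	13.53	16.32	5.04	1.23	5.29	48.82	2.44	1.45	68.87	7.96	0.10	17.21	162.62
JS	51°08′N, 124°10′E	GK	NA	5.21	26.83	20.48	5.60	1.94	10.90	64.32	4.62	3.33	97.76	3.43	5.11	12.90	181.27
TQ2	52°57′N, 122°52′E	GK	NA	5.57	22.26	18.96	4.68	1.71	15.92	68.72	3.34	1.77	79.15	6.96	6.91	17.72	965.42
HT	51°37′N, 123°59′E	GK	NA	4.11	12.91	27.38	5.19	0.96	7.90	73.70	3.70	1.19	50.63	2.13	1.44	4.40	61.70
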