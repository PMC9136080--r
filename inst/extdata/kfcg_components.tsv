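component_id	name	herbs	ob	caco2	dl	mw	source
MOL000006	Luteolin	MH	36.16	0.19	0.25		database
MOL000011	(2R,3R)-3-(4-hydroxy-3-methoxy-phenyl)-5-methoxy-2-methylol-2,3-dihydropyrano[5,6-h][1,4]benzodioxin-9-one		68.83	0.21	0.66		database
MOL000057	DIBP		49.63	0.85	0.13		database
MOL000098	Quercetin	MH,GC,BS,RS	46.43	0.05	0.28		database
MOL000105	Protocatechuic acid		25.37	0.10	0.04		database
MOL000114	Vanillic acid	CX	35.47	0.43	0.04	168.15	database
MOL000131	EIC		41.90	1.16	0.14		database
MOL000173	Wogonin	HQ	30.68	0.79	0.23		database
MOL000223	Caffeic acid	CX	25.76	0.21	0.05		database
MOL000239	Jaranol		50.83	0.61	0.29		database
MOL000354	Isorhamnetin		49.60	0.31	0.31		database
MOL000392	Formononetin		69.67	0.78	0.21		database
MOL000422	Kaempferol	MH,GC,BS,RS	41.88	0.26	0.24		database
MOL000497	Licochalcone a	GC	40.79	0.82	0.29		database
MOL000525	Norwogonin	HQ	39.40	0.60	0.21		database
MOL000635	Vanillin	CX	52.00	0.68	0.03		database
MOL000675	Oleic acid		33.13	1.17	0.14		database
MOL000771	p-coumaric acid		43.29	0.46	0.04		database
MOL000874	Paeonol	BS	28.79	0.93	0.04		database
MOL000953	CLR		37.87	1.43	0.68		database
MOL001490	bis [(2S)-2-ethylhexyl] benzene-1,2-dicarboxylate		43.59	0.98	0.35		database
MOL001494	Mandenol		42.00	1.46	0.19		database
MOL001689	Acacetin		34.97	0.67	0.24		database
MOL001755	24-Ethylcholest-4-en-3-one		36.08	1.46	0.76		database
MOL001789	Isoliquiritigenin	GC	85.32	0.44	0.15		database
MOL002295	Cinnamic acid	RG	19.68	0.91	0.03		database
MOL002467	6-gingerol	SJ	35.64	0.54	0.16		database
MOL002516	Zingerone	SJ	25.23	0.87	0.05	194.23	database
MOL002560	Chrysin		22.61	0.70	0.18		database
MOL002915	Salvigenin		49.07	0.86	0.33		database
MOL002932	Panicolin		76.26	0.84	0.29		database
MOL003896	7-Methoxy-2-methyl isoflavone		42.56	1.16	0.20		database
MOL004835	Glypallichalcone	GC	61.60	0.76	0.19		database
MOL004836	Echinatin	GC	66.58	0.38	0.17		database
MOL004951	Isoliquiritin	GC	8.61	-1.36	0.60		database
MOL004985	Icos-5-enoic acid		30.70	1.22	0.20		database
MOL004991	7-Acetoxy-2-methylisoflavone		38.92	0.74	0.26		database
MOL005842	Pectolinarigenin		41.17	0.70	0.30		database
MOL006129	6-methylgingediacetate2	SJ	48.73	0.55	0.32		database
MOL007207	Machiline		79.64	0.78	0.24		database
MOL007514	Methyl icosa-11,14-dienoate		39.67	1.47	0.23		database
MOL008698	Dihydrocapsaicin		47.07	0.98	0.19		database
MOL010921	Estrone		53.56	1.01	0.32		database
MOL011319	Truflex OBP		43.74	0.90	0.24		database
COM1	Benzoic acid	BS				122.12	literature
COM14	Ferulic acid	CX,RS				194.18	literature
COM15	L-tryptophan	CX				204.23	literature
COM24	Guanosine					283.24	literature
COM25	Uridine					244.20	literature
COM41	Caffeine					194.19	literature
COM47	Harmine					212.25	literature
COM48	Hyperoside					464.38	literature
COM50	Rhamnetin					316.26	literature
COM52	Yohimbine					354.44	literature
COM54	10-gingerol	SJ				350.50	literature
COM55	10-shogaol	SJ				332.50	literature
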