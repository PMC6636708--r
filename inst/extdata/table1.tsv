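family	n_sample	n_ethnologue	n_glottolog	root_age_yr	r_ethno_printed	t2_ethno_printed	r_glotto_printed	t2_glotto_printed	source
Kartvelian	NA	5	6	5500	0.00029	2390	0.00032	2127	Pagel et al. 2013
Dravidian	NA	85	80	4500	0.00034	2039	0.00034	2056	Kolipakam et al. 2018
Mayan	NA	35	33	6500	0.00055	1260	0.00054	1288	Atkinson 2006
Lezgic	20	9	10	3730	0.00059	1175	0.00062	1122	Kassian 2015
Inuit-Yupik	NA	11	12	4000	0.0006	1155	0.00062	1115	Pagel et al. 2013
Uralic	17	39	48	5300	0.00069	1005	0.00073	948	Honkola et al. 2013
Indo-European	103	449	584	8700	0.0007	990	0.00073	946	Bouckaert et al. 2012
Aslian	NA	18	19	4000	0.00072	963	0.00074	941	Dunn et al. 2011
Semitic	25	78	97	5614	0.00078	889	0.00081	850	Kitchen et al. 2009
Uto-Aztecan	NA	61	69	5000	0.00082	845	0.00085	818	Greenhill et al. 2023
Japonic	59	12	15	2182	0.00114	608	0.00124	558	Lee & Hasegawa 2011
Bantu	409	668	721	4800	0.00136	510	0.00137	505	Grollemund et al. 2015
Austronesian	398	1268	1276	5230	0.00137	506	0.00137	506	Gray et al. 2009
Chapacuran	10	5	12	1039	0.00155	447	0.00239	289	Birchall et al. 2016
Tupi-Guarani	NA	51	48	2500	0.00157	441	0.00155	447	Michael et al. 2015
Chukchee-Kamchatkan	NA	5	5	1000	0.00161	431	0.00161	430	Pagel et al. 2013
Turkic	26	41	44	2206	0.00168	413	0.00172	404	Hruschka et al. 2015
Pama-Nyungan	306	285	248	5671	0.00099	695	0.00097	712	Bouckaert et al. 2018
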