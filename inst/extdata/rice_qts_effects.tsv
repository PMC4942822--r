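trait	qts	chrom	allele	strategy	effect_type	effect	neglog10p	h2	total_h2
PH	rs25397447	1	A/G	GWA	a	2.61	10.74	8.91	45.63
PH	rs2745731	3	G/A	GWA	a	3.03	14.19	11.99	45.63
PH	rs36929057	3	G/A	GWA	a	2.50	9.96	8.21	45.63
PH	rs8819284	6	A/T	GWA	a	1.88	5.89	4.62	45.63
PH	rs14788399	7	A/T	GWA	a	-1.83	5.60	4.37	45.63
PH	rs4468159	11	C/T	GWA	a	-2.40	9.19	7.53	45.63
PH	rs37194796	3	C/T	QBA	a	2.85	10.36	9.89	37.22
PH	rs9040677	6	T/A	QBA	a	2.34	7.23	6.69	37.22
PH	rs9669459	6	T/C	QBA	a	2.24	6.65	6.10	37.22
PH	rs14788399	7	A/T	QBA	a	-2.72	9.54	9.04	37.22
PH	rs4468159	11	C/T	QBA	a	-2.12	6.06	5.50	37.22
PH	rs24562025	1	G/A	GBA	a	2.20	6.55	5.72	40.19
PH	rs10179007	6	C/G	GBA	a	3.01	11.59	10.63	40.19
PH	rs7478190	8	G/T	GBA	a	2.31	7.15	6.29	40.19
PH	rs489068	12	C/T	GBA	a	2.63	9.04	8.14	40.19
PH	rs10809004	12	C/A	GBA	a	-2.83	10.35	9.41	40.19
HD	rs12807091	1	T/C	GWA	a	1.58	5.57	4.67	41.56
HD	rs22665688	1	C/T	GWA	a	2.29	10.89	9.71	41.56
HD	rs26023433	1	C/T	GWA	a	1.41	4.54	3.71	41.56
HD	rs3033880	6	A/T	GWA	a	-2.49	12.78	11.53	41.56
HD	rs17909546	10	A/G	GWA	a	2.53	13.2	11.94	41.56
HD	rs14583697	1	G/A	QBA	a	2.28	13.94	9.53	55.95
HD	rs4139855	4	T/C	QBA	a	2.22	13.26	9.03	55.95
HD	rs2083119	5	C/T	QBA	a	-1.94	10.28	6.88	55.95
HD	rs3070122	6	G/A	QBA	a	-2.51	16.73	11.55	55.95
HD	rs14516781	7	A/T	QBA	a	2.02	11.09	7.46	55.95
HD	rs13634598	10	G/A	QBA	a	1.78	8.75	5.78	55.95
HD	rs17462383	10	T/C	QBA	a	1.77	8.66	5.72	55.95
HD	rs22139712	1	G/A	GBA	a	1.91	7.64	7.08	37.53
HD	rs32347548	4	T/C	GBA	a	1.66	5.95	5.36	37.53
HD	rs3112796	6	G/A	GBA	a	-1.78	6.77	6.19	37.53
HD	rs12634148	10	C/T	GBA	a	1.45	4.67	4.09	37.53
HD	rs17909546	10	A/G	GBA	a	2.24	10.31	9.79	37.53
HD	rs457324	12	C/T	GBA	a	1.61	5.60	5.02	37.53
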