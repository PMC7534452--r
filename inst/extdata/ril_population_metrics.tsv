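population	alt_parent	population_size	total_markers	gbs_markers	overall_length_cM	avg_interval_cM	max_interval_cM	pct_missing_gbs	pct_missing_postimpute
2RV	bla1	141	641	563	443.1	0.7	13.9	27.1	3.2
3RV	tsu0	145	1254	1175	449.8	0.4	6.4	23.6	1.4
4RV	nok1	144	1243	1158	462.6	0.4	7.1	23.0	1.1
6RV	ri0	144	1503	1419	489.5	0.3	7.5	16.6	0.8
8RV	cvi0	147	1615	1525	634.5	0.4	11.7	22.7	1.0
13RV	sha	148	796	711	417.4	0.5	7.9	20.2	1.3
17RV	ge0	149	1201	1119	485	0.4	5	23.6	1.2
19RV	can0	148	1561	1477	481.5	0.3	6.1	26.0	1.2
20RV	bur0	142	1344	1257	433	0.3	5.5	21.5	1.1
21RV	blh1	137	1074	1000	485.1	0.5	6.8	23.3	1.3
23RV	yo0	150	1351	1269	477.5	0.4	7.2	20.6	0.8
27RV	oy0	149	1349	1264	488.7	0.4	9.7	19.7	1.1
28RV	jea	147	1435	1348	482.2	0.3	6.5	17.8	0.8
29RV	ita0	137	1183	1096	430.8	0.4	9	16.4	0.9
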