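population	alt_parent	mean_pve_gbs	mean_pve_inra	mean_interval_gbs_cM	mean_interval_inra_cM	pct_interval_reduction	pct_detected_inra
2RV	bla1	10	9.7	25.2	29.1	-13.4	74.2
3RV	tsu0	10.1	9.6	23.3	28.1	-17.1	75.7
4RV	nok1	10.5	9.9	21.3	28.5	-25.3	75.9
6RV	ri0	10.3	9.5	24.5	34.1	-28.2	79.1
8RV	cvi0	10.6	9.8	24.2	36.9	-34.4	78
13RV	sha	9.8	9.3	21	27.1	-22.5	80.3
17RV	ge0	9.9	9.2	21.9	28.4	-22.9	78.2
19RV	can0	10.1	9.5	22.6	30.6	-26.1	75.7
20RV	bur0	10.1	9.5	23.8	32.8	-27.4	75.5
21RV	blh1	10.7	10	24.7	31.6	-21.8	68.7
23RV	yo0	10.2	9.4	21.1	29.9	-29.4	74.4
27RV	oy0	10	9.4	24.5	29.2	-16.1	74.9
28RV	jea	10.1	9.4	22.3	28.6	-22	78.6
29RV	ita0	10.7	10	22	27.5	-20	76.9
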