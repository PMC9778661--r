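quantity	system	value	sd
mean_gtp_sasa	wt	178.17	NA
mean_gtp_sasa	g14v	121.17	NA
mean_gtp_sasa	q63l	135.12	NA
bfe_total	wt	-227.08	0.25
bfe_total	g14v	-290.72	0.55
bfe_total	q63l	-262.51	1.83
bfe_res_G14	wt	-5.43	0.20
bfe_res_G14	g14v	-13.46	0.04
bfe_res_G14	q63l	-5.80	0.18
bfe_res_A15	wt	-7.19	0.22
bfe_res_A15	g14v	-7.77	0.17
bfe_res_A15	q63l	-7.66	0.28
bfe_res_C16	wt	-5.70	0.07
bfe_res_C16	g14v	-6.16	0.11
bfe_res_C16	q63l	-5.94	0.31
bfe_res_G17	wt	-7.82	0.29
bfe_res_G17	g14v	-8.27	0.20
bfe_res_G17	q63l	-8.14	0.16
bfe_res_K18	wt	-31.56	0.54
bfe_res_K18	g14v	-42.73	0.08
bfe_res_K18	q63l	-36.43	0.65
bfe_res_C20	wt	-7.95	0.18
bfe_res_C20	g14v	-7.94	0.06
bfe_res_C20	q63l	-7.95	0.11
bfe_res_Y34	wt	-11.14	0.40
bfe_res_Y34	g14v	-13.14	0.06
bfe_res_Y34	q63l	-12.06	0.14
bfe_res_MG	wt	-30.59	1.75
bfe_res_MG	g14v	-77.00	0.88
bfe_res_MG	q63l	-67.04	1.92
cluster_population	wt_cluster1	46	NA
cluster_population	wt_cluster3	18	NA
t37_hbond_occupancy_pct	g14v	99	NA
t37_hbond_occupancy_pct	q63l	78	NA
mean_site_waters	wt	5	NA
mean_site_waters	g14v	2	NA
mean_site_waters	q63l	3	NA
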