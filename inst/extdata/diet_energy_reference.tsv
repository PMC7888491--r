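diet_id	bw_kg	dm_intake_kg_per_d	attd_dm	attd_cp	attd_om	attd_ndf	attd_adf	attd_ee	attd_ge	n_intake_g_per_d	fecal_n_g_per_d	urinary_n_g_per_d	n_retention_g_per_d	me_intake_kj_per_mbw	thp_kj_per_mbw	fhp_kj_per_mbw	re_p_kj_per_mbw	re_l_kj_per_mbw	re_kj_per_mbw	rq_fed	rq_fasted	urinary_e_pct_de	me_de_pct	ne_me_pct	de_mj_per_kg_dm	me_mj_per_kg_dm	ne_mj_per_kg_dm
basal	47.82	1.30	89.6	87.2	91.0	57.3	52.4	47.9	88.7	39.3	5.0	13.5	20.7	1989	1214	775	304	471	775	1.10	0.81	2.5	96.6	77.5	16.08	15.54	12.05
EP-RSM-1	45.93	1.30	85.7	85.5	87.6	57.0	48.4	67.1	85.3	46.9	6.8	22.0	18.1	1979	1207	752	277	495	772	1.07	0.81	4.3	95.0	76.6	15.94	15.13	11.59
EP-RSM-2	47.53	1.30	86.2	85.9	88.1	51.3	43.2	67.2	85.9	48.4	6.8	16.3	25.3	1951	1235	816	373	344	716	1.06	0.81	3.6	95.6	78.0	15.95	15.24	11.89
SE-RSM-3	46.53	1.33	84.7	84.1	86.8	47.6	37.1	57.0	84.4	49.3	7.8	17.2	24.4	1949	1255	788	363	331	694	1.06	0.81	3.7	95.8	75.6	15.38	14.73	11.13
SE-RSM-4	48.07	1.35	85.8	85.4	87.6	49.9	45.2	49.5	85.2	50.6	7.4	17.6	25.6	1963	1273	828	374	316	691	1.06	0.80	3.9	95.3	77.1	15.55	14.83	11.43
SE-RSM-5	47.48	1.35	83.4	81.7	85.4	43.9	34.9	50.7	82.9	51.3	9.4	16.0	25.9	1934	1222	780	381	331	712	1.07	0.81	3.4	95.9	76.7	15.15	14.53	11.14
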