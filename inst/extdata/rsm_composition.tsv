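ingredient	source_type	dm_pct	ge_mj_per_kg_dm	cp_pct_dm	ee_pct_dm	starch_pct_dm	ndf_pct_dm	adf_pct_dm	cf_pct_dm	ash_pct_dm	glucosinolates_umol_per_g
EP-RSM-1	expeller-pressed	93.53	21.35	37.70	11.27	2.95	41.00	24.18	19.18	7.49	11.27
EP-RSM-2	expeller-pressed	91.65	20.56	39.75	6.55	4.43	32.34	21.75	15.04	6.94	39.42
SE-RSM-3	solvent-extracted	91.48	19.47	39.92	2.58	3.02	37.27	21.50	13.58	8.24	48.70
SE-RSM-4	solvent-extracted	89.90	19.60	41.03	1.71	3.12	30.84	20.04	14.23	7.22	9.12
SE-RSM-5	solvent-extracted	90.82	19.37	41.83	1.68	2.26	39.83	24.79	17.86	9.14	8.31
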