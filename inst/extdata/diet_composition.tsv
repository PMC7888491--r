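diet_id	dm_pct_asfed	cp_pct_asfed	ee_pct_asfed	starch_pct_asfed	ndf_pct_asfed	adf_pct_asfed	ash_pct_asfed
basal	88.17	16.62	2.42	46.26	11.02	3.06	4.08
EP-RSM-1	89.06	20.12	4.46	39.47	15.95	6.79	5.09
EP-RSM-2	88.71	20.69	3.78	39.06	13.92	6.08	4.84
SE-RSM-3	88.81	20.68	2.70	38.79	13.76	5.98	5.09
SE-RSM-4	88.69	20.78	2.69	40.04	13.93	6.13	4.95
SE-RSM-5	88.69	21.07	2.61	38.89	14.78	6.84	5.36
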