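ingredient	attd_cp	attd_om	attd_ndf	attd_adf	attd_ee	attd_ge	me_de_pct	ne_me_pct	de_mj_per_kg_dm	me_mj_per_kg_dm	ne_mj_per_kg_dm
EP-RSM-1	82.3	73.9	56.7	46.2	81.9	73.9	88.97	72.21	15.78	14.04	10.14
EP-RSM-2	83.4	76.3	41.0	36.9	87.5	76.1	91.38	80.13	15.65	14.30	11.46
SE-RSM-3	78.6	69.5	30.4	26.5	74.6	68.2	91.88	65.34	13.28	12.21	7.98
SE-RSM-4	82.1	73.6	46.5	40.4	61.6	71.8	89.54	75.14	14.07	12.60	9.47
SE-RSM-5	72.2	62.1	28.8	25.1	63.7	60.9	92.18	72.68	11.81	10.88	7.91
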