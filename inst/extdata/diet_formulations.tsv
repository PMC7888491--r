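diet_id	ingredient	as_fed_pct	role
basal	corn	72.50	mixture
basal	soybean_meal	25.00	mixture
basal	dicalcium_phosphate	0.90	mineral
basal	limestone	0.75	mineral
basal	salt	0.35	mineral
basal	vitamin_mineral_premix	0.50	mineral
EP-RSM-1	corn	58.00	mixture
EP-RSM-1	soybean_meal	20.00	mixture
EP-RSM-1	EP-RSM-1	19.50	test
EP-RSM-1	dicalcium_phosphate	0.90	mineral
EP-RSM-1	limestone	0.75	mineral
EP-RSM-1	salt	0.35	mineral
EP-RSM-1	vitamin_mineral_premix	0.50	mineral
EP-RSM-2	corn	58.00	mixture
EP-RSM-2	soybean_meal	20.00	mixture
EP-RSM-2	EP-RSM-2	19.50	test
EP-RSM-2	dicalcium_phosphate	0.90	mineral
EP-RSM-2	limestone	0.75	mineral
EP-RSM-2	salt	0.35	mineral
EP-RSM-2	vitamin_mineral_premix	0.50	mineral
SE-RSM-3	corn	58.00	mixture
SE-RSM-3	soybean_meal	20.00	mixture
SE-RSM-3	SE-RSM-3	19.50	test
SE-RSM-3	dicalcium_phosphate	0.90	mineral
SE-RSM-3	limestone	0.75	mineral
SE-RSM-3	salt	0.35	mineral
SE-RSM-3	vitamin_mineral_premix	0.50	mineral
SE-RSM-4	corn	58.00	mixture
SE-RSM-4	soybean_meal	20.00	mixture
SE-RSM-4	SE-RSM-4	19.50	test
SE-RSM-4	dicalcium_phosphate	0.90	mineral
SE-RSM-4	limestone	0.75	mineral
SE-RSM-4	salt	0.35	mineral
SE-RSM-4	vitamin_mineral_premix	0.50	mineral
SE-RSM-5	corn	58.00	mixture
SE-RSM-5	soybean_meal	20.00	mixture
SE-RSM-5	SE-RSM-5	19.50	test
SE-RSM-5	dicalcium_phosphate	0.90	mineral
SE-RSM-5	limestone	0.75	mineral
SE-RSM-5	salt	0.35	mineral
SE-RSM-5	vitamin_mineral_premix	0.50	mineral
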