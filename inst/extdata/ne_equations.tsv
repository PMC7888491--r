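equation	term	estimate	r2	aic	rmse	p_value	n
1	de	1.14	0.96	-14.14	0.36	0.005	8
1	cp	0.46	0.96	-14.14	0.36	0.005	8
1	intercept	-25.24	0.96	-14.14	0.36	0.005	8
2	me	0.85	0.88	-7.69	0.56	0.007	8
2	intercept	-1.48	0.88	-7.69	0.56	0.007	8
3	ge	4.62	0.82	-2.29	0.75	0.014	8
3	ee	-0.67	0.82	-2.29	0.75	0.014	8
3	intercept	-80.43	0.82	-2.29	0.75	0.014	8
4	ee	0.22	0.77	-0.53	0.84	0.018	8
4	ash	-0.79	0.77	-0.53	0.84	0.018	8
4	intercept	14.36	0.77	-0.53	0.84	0.018	8
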