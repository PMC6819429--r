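mineral	rsid	chromosome	nearby_gene	effect_allele	eaf	f_statistic	beta_exposure	se_exposure	p_exposure	beta_outcome	se_outcome	p_outcome	proxy_of	proxy_r2
magnesium	rs4072037	1	MUC1	T	0.53	136	0.010	0.001	2.1e-36	0.006	0.017	0.744		
magnesium	rs7965584	12	ATP2B1	A	0.71	60	0.007	0.001	1.1e-16	-0.021	0.020	0.286	rs10858938	0.95
magnesium	rs3925584	11	DCDC5	T	0.55	60	0.006	0.001	5.2e-16	0.009	0.017	0.607		
magnesium	rs11144134	9	TRPM6	C	0.08	55	0.011	0.001	8.2e-15	-0.022	0.032	0.505		
magnesium	rs13146355	4	SHROOM3	A	0.44	45	0.005	0.001	6.3e-13	-0.052	0.018	0.003		
magnesium	rs448378	3	MDS1	A	0.53	31	0.004	0.001	1.3e-08	0.003	0.017	0.864		
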