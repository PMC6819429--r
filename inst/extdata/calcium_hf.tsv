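mineral	rsid	chromosome	nearby_gene	effect_allele	eaf	f_statistic	beta_exposure	se_exposure	p_exposure	beta_outcome	se_outcome	p_outcome
calcium	rs1801725	3	CASR	T	0.15	299	0.071	0.004	8.9e-86	-0.032	0.027	0.236
calcium	rs1570669	20	CYP24A1	G	0.34	37	0.018	0.003	9.1e-12	0.014	0.018	0.457
calcium	rs1550532	2	DGKD	C	0.31	37	0.018	0.003	8.2e-11	0.004	0.018	0.829
calcium	rs7481584	11	CARS	G	0.70	37	0.018	0.003	1.2e-10	0.003	0.018	0.888
calcium	rs780094	2	GCKR	T	0.42	37	0.017	0.003	1.3e-10	0.008	0.017	0.652
calcium	rs7336933	13	DGKH/KIAA0564	G	0.85	31	0.022	0.004	9.1e-10	-0.013	0.024	0.594
calcium	rs10491003	10	GATA3	T	0.09	31	0.027	0.005	4.8e-09	-0.030	0.031	0.344
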