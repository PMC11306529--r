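# intercept: 0
probe	coef	gene	rho	cluster	coef_expr
cg00954633	-0.42	PALM	0.64	Cell cycle	-0.27
cg25929976	-0.20	CTSC	-0.52	Cell cycle	0.10
cg19901005	-0.18	SH2D2A	-0.58	Cell cycle	0.10
cg12445422	-0.16	YBX1	-0.67	Cell cycle	0.10
cg16004056	-0.09	TBX19	-0.68	Cell cycle	0.06
cg12772314	-0.07	ATP6AP1L	0.41	Cell cycle	-0.03
cg14209784	0.97	TNFAIP3	0.64	Estrogen response 1	0.62
cg05870586	0.39	GALNT10	-0.56	Estrogen response 1	-0.22
cg08287887	0.08	JMJD8	-0.60	Estrogen response 1	-0.05
cg18229767	-0.09	TNFSF14	-0.60	Immune	0.06
cg09524658	-0.08	MLKL	-0.62	Immune	0.05
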