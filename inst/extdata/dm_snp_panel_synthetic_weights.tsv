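snp_id	chrom	pos	gene	risk_allele	other_allele	weight	raf
rs17106184	1	50909985	FAF1	G	A	0.072768	0.91
rs10923931	1	120517959	NOTCH2	T	G	0.065572	0.1
rs2075423	1	214154719	PROX1	G	T	0.03321	0.63
rs2867125	2	622827	TMEM18	C	T	0.03941	0.82
rs780094	2	27741237	GCKR	C	T	0.039357	0.6
rs10203174	2	43690030	THADA	C	T	0.037117	0.88
rs243088	2	60568745	BCL11A	T	A	0.028654	0.46
rs11123406	2	111950541	BCL2L11	T	C	0.057081	0.35
rs998451	2	135429288	TMEM163	A	G	0.038365	0.41
rs4410242	2	161192070	RBMS1	G	A	0.062494	0.81
rs3923113	2	165501849	GRB14	A	C	0.024616	0.61
rs2943640	2	227093585	IRS1	C	A	0.060749	0.64
rs1801282	3	12393125	PPARG	C	G	0.051112	0.86
rs7612463	3	23336450	UBE2E2	C	A	0.045372	0.9
rs831571	3	64048297	PSMD6	C	T	0.050837	0.82
rs6795735	3	64705365	ADAMTS9	C	T	0.063058	0.59
rs11717195	3	123082398	ADCY5	T	C	0.043474	0.78
rs4402960	3	185511687	IGF2BP2	T	G	0.062476	0.31
rs16861329	3	186666461	ST64GAL1	C	T	0.032321	0.87
rs6808574	3	187740523	LPP	C	T	0.057836	0.61
rs4458523	4	6289986	WFS1	G	T	0.038832	0.6
rs7674212	4	103988899	CISD2	G	T	0.022171	0.58
rs2706785	4	122660250	TMEM155	G	A	0.036868	0.03
rs6813195	4	153520475	TMEM154	C	T	0.054228	0.73
rs1996546	4	185714289	ACSL1	G	T	0.053764	0.85
rs702634	5	53271420	ARL15	A	G	0.050363	0.68
rs459193	5	55806751	ANKRD55	G	A	0.042367	0.74
rs6878122	5	76427311	ZBED3	G	A	0.016094	0.29
rs329122	5	133864599	PHF15	A	G	0.053051	0.4
rs9505118	6	7290437	SSR1/RREB1	A	G	0.044415	0.6
rs7756992	6	20679709	CDKAL1	G	A	0.046407	0.29
rs3130501	6	31136453	POU5F1/TCF19	G	A	0.033862	0.73
rs2050188	6	32339897	HLA-DRB5	T	C	0.053342	0.63
rs9271775	6	32594328	HLA-DQA1	T	C	0.055989	0.82
rs9470794	6	38106844	ZFAND3	T	C	0.026533	0.92
rs4407733	6	137299152	IL20RA	A	G	0.033106	0.53
rs622217	6	160766770	SLC22A3	T	C	0.049376	0.47
rs17168486	7	14898282	DGKB	T	C	0.017213	0.18
rs849135	7	28196413	JAZF1	G	A	0.051406	0.5
rs10278336	7	44245363	GCK	A	G	0.018287	0.58
rs6467136	7	127164958	GCC1	A	G	0.061253	0.46
rs13233731	7	130437689	KLF14	G	A	0.043088	0.51
rs9648716	7	140612163	BRAF	T	A	0.037142	0.14
rs1182397	7	157031407	MNX1	G	T	0.041706	0.84
rs12681990	8	36859186	KCNU1	C	T	0.066432	0.19
rs516946	8	41519248	ANK1	C	T	0.07028	0.76
rs7845219	8	95937502	TP53INP1	T	C	0.021298	0.54
rs3802177	8	118185025	SLC30A8	G	A	0.0356	0.69
rs7041847	9	4287466	GLIS3	A	G	0.044654	0.51
rs17584499	9	8879118	PTPRD	T	C	0.047257	0.2
rs10811661	9	22134094	CDKN2A/B	T	C	0.059513	0.83
rs17791513	9	81905590	TLE4	A	G	0.025267	0.93
rs2796441	9	84308948	TLE1	G	A	0.081967	0.6
rs495828	9	136154867	ABO	T	G	0.064006	0.24
rs11257655	10	12307894	CDC123	T	C	0.037787	0.21
rs1802295	10	70931474	VPS26A	T	C	0.057446	0.32
rs12571751	10	80942631	ZMIZ1	A	G	0.057574	0.53
rs1111875	10	94462882	HHEX/IDE	C	T	0.055298	0.59
rs7903146	10	114758349	TCF7L2	T	C	0.079105	0.28
rs10886471	10	121149403	GRK5	T	C	0.0629	0.45
rs2421016	10	124167512	PLEKHA1	C	T	0.022406	0.5
rs2334499	11	1696849	DUSP8	T	C	0.029227	0.4
rs163184	11	2847069	KCNQ1	G	T	0.064726	0.5
rs5215	11	17408630	KCNJ11	C	T	0.060353	0.36
rs3736505	11	43876435	HSD17B12	G	A	0.052691	0.3
rs11227234	11	65365171	MAP3K11	T	G	0.041528	0.24
rs1552224	11	72433098	ARAP1 (CENTD2)	A	C	0.106516	0.84
rs10830963	11	92708710	MTNR1B	G	C	0.058946	0.29
rs11063069	12	4374373	CCND2	G	A	0.059718	0.21
rs10842994	12	27965150	KLHDC5	C	T	0.063764	0.79
rs2261181	12	66212318	HMGA2	T	C	0.036641	0.09
rs7955901	12	71433293	TSPAN8	C	T	0.030536	0.45
rs12427353	12	121426901	HNF1B	G	C	0.044397	0.82
rs1727294	12	123616514	MPHOSPH9	G	A	0.022606	0.79
rs825476	12	124568456	CCDC92	T	C	0.064073	0.57
rs10507349	13	26781528	RNF6	G	A	0.044915	0.77
rs576674	13	33554302	KL	G	A	0.042885	0.17
rs1359790	13	80717156	SPRY2	G	A	0.053441	0.72
rs7985179	13	91940169	MIR17HG	T	A	0.047691	0.75
rs17109256	14	79939993	NRXN3	A	G	0.027631	0.22
rs7403531	15	38822905	RASGRP1	T	C	0.06649	0.21
rs4502156	15	62383155	C2CD4A	C	T	0.037452	0.41
rs7178572	15	77747190	HMG20A	G	A	0.061896	0.7
rs11634397	15	80432222	ZFAND6	G	A	0.046876	0.68
rs2028299	15	90374257	AP3S2	C	A	0.054757	0.28
rs12899811	15	91544076	PRC1	G	A	0.058891	0.31
rs9940149	16	300641	ITFG3	G	A	0.063416	0.81
rs9936385	16	53819169	FTO	C	T	0.025675	0.41
rs7202877	16	75247245	BCAR1	T	G	0.064476	0.89
rs2925979	16	81534790	CMIP	T	C	0.060153	0.3
rs391300	17	2216258	SRR	C	T	0.013838	0.64
rs8068804	17	3985864	ZZEF1	A	G	0.050686	0.32
rs17676067	17	9791375	GLP2R	C	T	0.029262	0.28
rs11651052	17	36102381	HNF1B	G	A	0.021474	0.53
rs15563	17	47005193	GIP	G	A	0.034856	0.53
rs12970134	18	57884750	MC4R	A	G	0.042379	0.26
rs10401969	19	19407718	CILP2	C	T	0.038175	0.08
rs3786897	19	33893008	PEPD	A	G	0.057981	0.58
rs8108269	19	46158513	GIPR	G	T	0.036445	0.31
rs4812829	20	42989267	HNF4A	A	G	0.050659	0.18
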