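gene_id	gene_symbol	fold_change
1300	COL10A1	42.74
3007	HIST1H1D	29.72
8366	HIST1H4B	25.58
6286	S100P	25.19
1301	COL11A1	24.72
3627	CXCL10	17.83
4283	CXCL9	15.88
1387	CREBBP	12.83
27299	ADAMDEC1	12.78
54986	ULK4	12.46
55771	PRR11	12.02
54790	TET2	11.25
6241	RRM2	10.60
3433	IFIT2	10.49
6999	TDO	29.73
1656	DDX	69.72
55088	C10orf11	89.37
9648	GCC	29.24
6696	SPP	18.92
2803	GOLGA	48.57
83540	NUF	27.73
10112	KIF20A	7.66
9833	MELK	7.59
55165	CEP5	57.50
10142	AKAP	97.44
9447	AIM	27.42
54443	ANLN	5.79
6710	SPTB	5.71
7272	TTK	5.64
10635	RAD51AP	15.49
4069	LYZ	5.37
55183	RIF	15.34
891	CCNB	15.34
91543	RSAD	25.31
81610	FAM83D	5.24
64581	CLEC7A	5.10
10051	SMC	45.02
4085	MAD2L	14.96
55872	PBK	4.83
991	CDC20	4.82
9221	NOLC	14.74
2124	EVI2B	4.66
375248	ANKRD3	64.66
1164	CKS	24.64
1230	CCR	14.62
890	CCNA	24.56
127933	UHMK	14.49
10274	STAG	14.45
597	BCL2A	14.43
55355	HJURP	4.41
54210	TREM	14.36
253558	LCLAT	14.26
2706	GJB	27.33
6498	SKIL	7.13
219285	SAMD9L	7.06
10261	IGSF	67.01
2335	FN	16.95
699	BUB	16.75
1058	CENPA	6.75
332	BIRC	56.73
51203	NUSAP	16.59
259266	ASPM	6.54
1063	CENPF	6.49
165918	RNF16	86.44
9232	PTTG	16.34
5996	RGS	16.07
29089	UBE2T	5.96
22974	TPX	25.94
4321	MMP1	25.91
983	CDK	15.89
85444	LRRCC	15.87
29121	CLEC2D	3.83
4090	SMAD	53.80
2123	EVI2A	3.80
57695	USP3	73.79
133418	EMB	3.76
4131	MAP1B	3.76
9787	DLGAP	53.75
9768	KIAA010	13.74
54625	PARP1	43.73
2215	FCGR3B	3.71
9134	CCNE	23.70
3117	HLA-DQA	13.68
10380	BPNT	13.67
79056	PRRG	43.63
10673	TNFSF13B	3.63
8467	SMARCA	53.61
115908	CTHRC	13.61
3428	IFI1	63.61
1520	CTSS	3.61
10797	MTHFD	23.57
55681	SCYL	23.57
9749	PHACTR	23.57
94240	EPSTI	13.56
64151	NCAPG	3.51
25879	DCAF1	33.51
1033	CDKN	34.24
79801	SHCBP	14.23
126731	C1orf9	64.21
6772	STAT	14.20
55729	ATF7IP	4.14
6713	SQLE	4.14
157570	ESCO	24.10
79871	RPAP	24.09
9493	KIF2	34.09
4751	NEK	24.05
10631	POSTN	4.03
23515	MORC	34.02
7153	TOP2A	4.02
10403	NDC80	4.00
10915	TCERG	13.99
57650	KIAA152	43.99
23049	SMG	13.93
80231	CXorf2	13.87
5111	PCNA	3.86
79682	MLF1IP	3.11
29123	ANKRD1	13.09
5429	POLH	3.09
701	BUB1B	3.07
200030	NBPF1	13.06
55677	IWS	13.06
160418	TMTC	33.04
9147	NEMF	3.04
11320	MGAT4A	3.04
5238	PGM	33.03
2820	GPD	23.02
388886	FAM211B	3.01
7852	CXCR	43.00
57082	CASC	52.99
22926	ATF	62.98
7594	ZNF4	32.98
968	CD6	82.97
7171	TPM	42.96
11004	KIF2C	2.96
10808	HSPH	12.95
84909	C9orf	32.94
1894	ECT	22.93
1629	DBT	2.92
116969	ART	52.90
3227	HOXC1	12.88
116064	LRRC5	83.47
29899	GPSM	23.47
135114	HINT	33.45
27333	GOLIM	43.43
55839	CENPN	3.43
23213	SULF	13.41
81671	VMP	13.39
9889	ZBED	43.36
3092	HIP	13.34
51512	GTSE	13.34
92797	HELB	3.34
51426	POLK	3.30
5611	DNAJC	33.30
6596	HLTF	3.28
9910	RABGAP1L	3.25
528	ATP6V1C	13.23
3833	KIFC	13.23
197131	UBR	13.20
29923	HILPDA	3.20
28998	MRPL1	33.19
58527	C6orf11	53.19
79000	C1orf13	53.19
9857	CEP350	3.18
84296	GINS	43.18
81034	SLC25A3	23.15
55723	ASF1B	3.14
7110	TMF	13.14
84081	NSRP	13.14
23075	SWAP70	3.12
6726	SRP	92.69
55215	FANCI	2.68
57590	WDFY	12.67
55142	HAUS	22.66
23047	PDS5B	2.66
5373	PMM	22.66
11065	UBE2C	2.66
23085	ERC	12.66
389197	C4orf50	2.65
11260	XPOT	2.65
29980	DONSON	2.65
64399	HHIP	2.64
6453	ITSN	12.63
29108	PYCARD	2.63
9877	ZC3H11A	2.62
3149	HMGB	32.87
10437	IFI30	2.87
57489	ODF2L	2.87
2151	F2RL	22.86
23215	PRRC2C	2.85
128710	C20orf9	42.85
23594	ORC	62.84
5205	ATP8B	12.83
51430	C1orf	92.80
57405	SPC2	52.80
112401	BIRC	82.80
3606	IL1	82.80
115362	GBP	52.80
50515	CHST1	12.79
83461	CDCA	32.79
10744	PTTG	22.78
51765	MST	42.77
10926	DBF	42.76
27125	AFF	42.75
10615	SPAG	52.75
55143	CDCA	82.74
51602	NOP5	82.74
51478	HSD17B	72.73
2209	FCGR1A	2.73
9958	USP1	52.72
5469	MED	12.72
8813	DPM	12.70
6731	SRP7	22.70
9991	PTBP	32.70
79866	BORA	2.41
7072	TIA	12.40
55632	G2E	32.40
2213	FCGR2B	2.40
3987	LIMS	12.39
829	CAPZA	12.39
26973	CHORDC	12.38
435	ASL	2.38
29979	UBQLN	12.38
8548	BLZF	12.37
9694	TTC3	52.37
55055	ZWILCH	2.36
4481	MSR	12.36
10213	PSMD1	42.35
9966	TNFSF1	52.35
81624	DIAPH	32.62
79723	SUV39H	22.61
55789	DEPDC1B	2.61
10097	ACTR	22.59
23036	ZNF29	22.58
22936	ELL	22.57
8477	GPR6	52.57
23397	NCAPH	2.57
3015	H2AFZ	2.54
55749	CCAR	12.53
25937	WWTR	12.52
360023	ZBTB4	12.51
5080	PAX	62.51
4193	MDM	22.51
24137	KIF4A	2.51
9212	AURKB	2.51
168850	ZNF800	2.50
55109	AGGF	12.49
23185	LARP4B	2.49
51571	FAM49B	2.49
51077	FCF	12.49
23167	EFR3A	2.49
23468	CBX	52.48
5396	PRRX	12.48
10096	ACTR	32.47
10308	ZNF26	72.47
6782	HSPA1	32.47
3832	KIF1	12.47
917	CD3G	2.47
80821	DDHD	12.46
52	ACP	12.46
4179	CD4	62.46
10499	NCOA	22.44
60558	GUF	12.44
55676	SLC30A	62.43
6646	SOAT	12.43
5440	POLR2K	2.43
84955	NUDCD	12.42
54739	XAF	12.42
84295	PHF	62.23
7295	TXN	2.23
2710	GK	2.23
10905	MAN1A	22.22
6780	STAU	12.22
51582	AZIN	12.35
54843	SYTL	22.34
9039	UBA	32.33
933	CD2	22.33
5685	PSMA	42.33
9885	OSBPL	22.33
9262	STK17B	2.33
56942	C16orf6	12.32
10767	HBS1L	2.32
87178	PNPT	12.32
6303	SAT	12.32
7316	UBC	2.32
4205	MEF2A	2.32
85465	EPT	12.31
84640	USP3	82.31
5810	RAD	12.30
64397	ZFP10	62.29
5706	PSMC	62.29
22948	CCT	52.29
10672	GNA1	32.29
339344	MYPOP	2.28
7292	TNFSF	42.28
57103	C12orf	52.28
388403	YPEL	22.28
54876	DCAF1	62.27
113235	SLC46A	12.27
11177	BAZ1A	2.27
339175	METTL2A	2.26
26586	CKAP	22.26
55785	FGD	62.26
24145	PANX	12.25
253461	ZBTB3	82.25
23232	TBC1D1	22.25
995	CDC25C	2.25
55974	SLC50A	12.25
472	ATM	2.25
23008	KLHDC10	2.24
10024	TROAP	2.24
9521	EEF1E	12.24
7402	UTRN	2.09
55589	BMP2K	2.08
158747	MOSPD	22.08
56886	UGGT	12.07
203100	HTRA	42.07
10282	BET	12.22
134430	WDR3	62.21
4299	AFF	12.21
6747	SSR	32.21
7334	UBE2N	2.21
5965	RECQL	2.21
4605	MYBL	22.2
6093	ROCK	12.19
161725	OTUD7A	2.19
23518	R3HDM	12.18
2239	GPC	42.18
28977	MRPL4	22.18
64859	OBFC2A	2.18
3845	KRAS	2.18
51388	NIP	72.18
7586	ZKSCAN	12.18
10762	NUP50	2.17
7328	UBE2H	2.17
10730	YME1L	12.17
23093	TTLL	52.17
6790	AURKA	2.17
22889	KIAA090	72.17
10875	FGL	22.17
23161	SNX1	32.17
9169	SCAF1	12.16
1788	DNMT3A	2.15
9088	PKMYT	12.15
23033	DOPEY	12.13
89882	TPD52L	32.13
6556	SLC11A	12.13
64216	TFB2M	2.13
3071	NCKAP1L	2.13
51068	NMD	32.13
509	ATP5C	12.13
953	ENTPD	12.13
51105	PHF20L	12.13
5062	PAK	22.13
9205	ZMYM	52.12
55157	DARS	22.12
8520	HAT	12.11
79739	TTLL	72.11
9495	AKAP	52.10
3181	HNRNPA2B	12.10
55279	ZNF65	42.07
54499	TMCO	12.07
81930	KIF18A	2.07
142686	ASB1	42.06
55209	SETD	52.06
9736	USP3	42.04
116285	ACSM	12.04
2201	FBN	22.04
963	CD5	32.04
55159	RFWD	32.03
9871	SEC24D	2.03
9887	SMG	72.02
23376	UFL	12.02
79646	PANK	32.01
50613	UBQLN	32.00
201595	STT3B	2.00
59345	GNB	41.99
5876	RABGGTB	1.99
79820	CATSPERB	1.99
6637	SNRPG	1.99
51330	TNFRSF12A	1.99
9928	KIF1	41.99
286097	EFHA	21.98
9131	AIFM	11.98
488	ATP2A	21.98
23042	PDXDC	11.98
7114	TMSB4X	1.98
9123	SLC16A	31.98
54454	ATAD2B	1.97
23143	LRCH	11.97
4212	MEIS	21.97
1457	CSNK2A	11.97
80012	PHC	31.97
128497	SPATA2	51.96
186	AGTR	21.96
53981	CPSF	21.96
56996	SLC12A	91.96
1584	CYP11B	11.96
133619	PRRC	11.96
4288	MKI6	71.96
9014	TAF1B	1.96
55858	TMEM16	51.96
2212	FCGR2A	1.96
389898	UBE2NL	2.10
29850	TRPM	52.10
3070	HELLS	2.10
331	XIAP	2.09
55751	TMEM184C	2.09
2146	EZH	22.09
26057	ANKRD1	71.95
128061	C1orf13	11.95
64090	GAL3ST	21.94
130507	UBR	31.93
2298	FOXD	41.93
123169	LEO	11.93
57187	THOC	21.93
148789	B3GALNT	21.93
58508	MLL	31.92
5701	PSMC	21.92
148066	ZNRF	41.92
6670	SP	31.92
10075	HUWE	11.96
220988	HNRNPA	31.96
80146	UXS	11.95
122011	CSNK1A1L	1.95
150468	CKAP2L	1.95
84624	FNDC	11.95
7332	UBE2L	31.92
3336	HSPE	11.92
54800	KLHL2	41.92
2290	FOXG	11.91
50848	F11R	1.91
10627	MYL12A	1.91
5074	PAWR	1.91
6476	SI	1.91
1009	CDH1	11.90
29066	ZC3H7A	1.90
51319	RSRC	11.90
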