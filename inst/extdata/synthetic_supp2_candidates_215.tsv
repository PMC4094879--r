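# Synthetic stand-in for the full 215-row candidate table: the 67
# published significant rows (fdr < 0.05) are verbatim; the remaining
# 148 rows are synthetic fillers with fdr >= 0.05 and SYNP/SYNG ids.
gene	gene_name	betweenness	fdr
ENSP00000281821	EPHA4	339	0.000
ENSP00000245323	EFNB2	335	0.000
ENSP00000357177	ARHGEF11	142	0.000
ENSP00000312697	DMAP1	88	0.000
ENSP00000227638	PANX1	72	0.000
ENSP00000235310	MAD2L2	72	0.000
ENSP00000258428	REV1	72	0.000
ENSP00000265727	ADAM22	72	0.000
ENSP00000293831	EIF4A1	72	0.000
ENSP00000302719	KCNAB3	72	0.000
ENSP00000329797	CADM1	72	0.000
ENSP00000335434	WDR20	72	0.000
ENSP00000341138	EPB41L3	72	0.000
ENSP00000351697	REV3L	72	0.000
ENSP00000354778	CNTNAP2	72	0.000
ENSP00000356150	MDM4	72	0.000
ENSP00000361366	SFTPD	72	0.000
ENSP00000369218	RBM17	72	0.000
ENSP00000370119	SMN2	72	0.000
ENSP00000377446	SUCLG1	210	0.001
ENSP00000245304	RAP2A	72	0.001
ENSP00000275815	EPHA1	72	0.001
ENSP00000328511	KCNA4	72	0.001
ENSP00000399511	TNIK	72	0.001
ENSP00000304169	PITX2	210	0.002
ENSP00000263923	KDR	104	0.002
ENSP00000229595	ASF1A	72	0.002
ENSP00000252699	ACTN4	72	0.002
ENSP00000263208	HIRA	72	0.002
ENSP00000330633	CNTN2	72	0.002
ENSP00000295600	MITF	138	0.003
ENSP00000276072	TAF1	72	0.003
ENSP00000360157	FOXD3	6	0.003
ENSP00000350941	SRC	421	0.004
ENSP00000361125	VEGFA	164	0.004
ENSP00000271628	SF3B4	75	0.004
ENSP00000264010	CTCF	72	0.004
ENSP00000226091	EFNB3	67	0.006
ENSP00000358309	EPHA7	2	0.006
ENSP00000358918	SUFU	72	0.007
ENSP00000316879	EIF4G1	72	0.011
ENSP00000260653	SIX3	2	0.012
ENSP00000352516	DNMT1	90	0.016
ENSP00000358716	DDX20	72	0.017
ENSP00000357393	EFNA3	50	0.018
ENSP00000344456	CTNNB1	607	0.020
ENSP00000341680	DTNBP1	66	0.020
ENSP00000297904	FIGF	2	0.021
ENSP00000265165	LEF1	134	0.022
ENSP00000347948	TNFRSF14	68	0.023
ENSP00000288986	NCK1	78	0.027
ENSP00000261937	FLT4	2	0.029
ENSP00000333919	BTLA	68	0.030
ENSP00000332549	GRIN2A	58	0.032
ENSP00000376765	PIAS3	4	0.033
ENSP00000386165	CEBPD	38	0.035
ENSP00000361818	SDC4	1	0.035
ENSP00000348307	SIRPA	34	0.036
ENSP00000344666	NF2	1	0.037
ENSP00000219255	PARD6A	72	0.038
ENSP00000204961	EFNB1	5	0.039
ENSP00000172229	NGFR	72	0.043
ENSP00000344115	CDH5	24	0.043
ENSP00000405041	POU5F1	6	0.045
ENSP00000360532	CDC5L	6	0.046
ENSP00000340944	PTPN11	112	0.047
ENSP00000295897	ALB	72	0.047
SYNP0003435288	SYNG130	70	0.064
SYNP0007347784	SYNG138	19	0.070
SYNP0000241574	SYNG140	48	0.081
SYNP0008596723	SYNG117	38	0.082
SYNP0001320675	SYNG091	43	0.089
SYNP0002144963	SYNG127	8	0.091
SYNP0005805747	SYNG014	72	0.097
SYNP0000817430	SYNG106	75	0.100
SYNP0003721735	SYNG118	65	0.101
SYNP0000555283	SYNG060	54	0.102
SYNP0009306436	SYNG089	40	0.115
SYNP0000086758	SYNG043	5	0.120
SYNP0006213191	SYNG009	46	0.127
SYNP0008497413	SYNG068	6	0.131
SYNP0009825274	SYNG095	80	0.172
SYNP0004303982	SYNG059	24	0.176
SYNP0005086122	SYNG139	46	0.180
SYNP0001997707	SYNG042	13	0.182
SYNP0003365157	SYNG026	6	0.182
SYNP0001353069	SYNG023	55	0.201
SYNP0005884063	SYNG021	64	0.205
SYNP0001873177	SYNG112	44	0.212
SYNP0009426538	SYNG125	34	0.215
SYNP0002104403	SYNG116	65	0.224
SYNP0003836218	SYNG061	18	0.225
SYNP0007468595	SYNG069	33	0.228
SYNP0002995896	SYNG084	56	0.231
SYNP0004907903	SYNG105	79	0.236
SYNP0009972627	SYNG092	73	0.239
SYNP0007021695	SYNG006	60	0.240
SYNP0008178985	SYNG093	15	0.255
SYNP0000884922	SYNG090	19	0.259
SYNP0000903534	SYNG054	56	0.268
SYNP0006918803	SYNG083	20	0.270
SYNP0001899406	SYNG046	8	0.288
SYNP0006337368	SYNG035	8	0.293
SYNP0005033962	SYNG064	60	0.297
SYNP0007763903	SYNG047	74	0.299
SYNP0005045466	SYNG146	3	0.318
SYNP0003370745	SYNG067	4	0.320
SYNP0007675999	SYNG002	23	0.326
SYNP0002775373	SYNG040	46	0.331
SYNP0002220017	SYNG036	37	0.335
SYNP0001604320	SYNG052	65	0.341
SYNP0005852494	SYNG001	6	0.345
SYNP0009518242	SYNG131	76	0.359
SYNP0004816208	SYNG013	24	0.366
SYNP0006751473	SYNG133	4	0.382
SYNP0000216269	SYNG128	61	0.388
SYNP0002439934	SYNG032	47	0.403
SYNP0001613494	SYNG049	8	0.407
SYNP0009153825	SYNG100	63	0.418
SYNP0006581740	SYNG056	13	0.420
SYNP0005603910	SYNG076	22	0.440
SYNP0004389580	SYNG087	10	0.441
SYNP0003615399	SYNG008	8	0.450
SYNP0009075927	SYNG020	19	0.453
SYNP0003096878	SYNG094	62	0.457
SYNP0001527637	SYNG145	18	0.457
SYNP0001837698	SYNG055	61	0.460
SYNP0008714864	SYNG011	16	0.467
SYNP0004814649	SYNG065	4	0.493
SYNP0000197642	SYNG141	42	0.494
SYNP0003449334	SYNG016	52	0.495
SYNP0001721410	SYNG078	16	0.505
SYNP0001861075	SYNG024	38	0.518
SYNP0005846895	SYNG113	15	0.523
SYNP0008083479	SYNG004	7	0.523
SYNP0004189360	SYNG081	11	0.525
SYNP0003787739	SYNG085	11	0.535
SYNP0002659485	SYNG098	18	0.539
SYNP0007666289	SYNG018	20	0.548
SYNP0002528573	SYNG080	1	0.548
SYNP0007659771	SYNG109	71	0.549
SYNP0000748792	SYNG119	31	0.557
SYNP0006768198	SYNG033	55	0.559
SYNP0000381958	SYNG063	7	0.563
SYNP0004483466	SYNG072	36	0.565
SYNP0003333056	SYNG070	68	0.570
SYNP0000731116	SYNG086	77	0.576
SYNP0005299008	SYNG123	8	0.576
SYNP0005265626	SYNG096	15	0.577
SYNP0002091029	SYNG025	11	0.581
SYNP0005727410	SYNG147	13	0.586
SYNP0005923535	SYNG126	78	0.588
SYNP0003868778	SYNG022	75	0.601
SYNP0008174252	SYNG121	56	0.602
SYNP0008246530	SYNG038	7	0.609
SYNP0006140225	SYNG050	12	0.611
SYNP0009768218	SYNG003	15	0.612
SYNP0000147348	SYNG075	70	0.617
SYNP0005763434	SYNG044	30	0.625
SYNP0005602099	SYNG102	8	0.637
SYNP0007554243	SYNG111	74	0.658
SYNP0000182842	SYNG028	39	0.686
SYNP0001777701	SYNG005	6	0.689
SYNP0000337272	SYNG019	40	0.694
SYNP0004195930	SYNG079	56	0.696
SYNP0000621418	SYNG031	75	0.703
SYNP0002546907	SYNG066	8	0.709
SYNP0004409219	SYNG088	49	0.710
SYNP0000958267	SYNG124	16	0.713
SYNP0004529391	SYNG057	32	0.734
SYNP0008225734	SYNG104	2	0.740
SYNP0003191883	SYNG030	76	0.742
SYNP0001842393	SYNG039	48	0.750
SYNP0007558379	SYNG115	21	0.756
SYNP0005102374	SYNG051	18	0.760
SYNP0001326064	SYNG107	52	0.770
SYNP0004095787	SYNG082	35	0.772
SYNP0000210353	SYNG103	72	0.777
SYNP0002180837	SYNG037	62	0.793
SYNP0000910254	SYNG048	79	0.803
SYNP0004816485	SYNG108	48	0.803
SYNP0001998294	SYNG012	67	0.811
SYNP0005614701	SYNG099	1	0.812
SYNP0008031386	SYNG010	3	0.823
SYNP0002833978	SYNG122	56	0.824
SYNP0001906958	SYNG136	61	0.831
SYNP0002596931	SYNG134	68	0.836
SYNP0004029406	SYNG114	52	0.836
SYNP0007515936	SYNG110	19	0.852
SYNP0003466336	SYNG071	76	0.862
SYNP0007426489	SYNG137	12	0.864
SYNP0001772327	SYNG132	45	0.879
SYNP0003179652	SYNG062	9	0.886
SYNP0008904632	SYNG148	6	0.891
SYNP0008872932	SYNG058	25	0.914
SYNP0006410164	SYNG015	14	0.914
SYNP0009524937	SYNG077	12	0.917
SYNP0005917205	SYNG143	37	0.934
SYNP0005324944	SYNG129	32	0.935
SYNP0003938456	SYNG073	9	0.938
SYNP0002160354	SYNG029	57	0.944
SYNP0003771626	SYNG027	59	0.946
SYNP0006557024	SYNG045	56	0.946
SYNP0000190544	SYNG017	50	0.948
SYNP0003113700	SYNG101	33	0.952
SYNP0008199194	SYNG034	68	0.958
SYNP0002895950	SYNG135	37	0.962
SYNP0007176348	SYNG007	8	0.964
SYNP0008392312	SYNG142	72	0.966
SYNP0001645533	SYNG120	7	0.969
SYNP0009902204	SYNG097	32	0.978
SYNP0000133670	SYNG041	8	0.980
SYNP0006945615	SYNG144	11	0.985
SYNP0008257153	SYNG053	24	0.994
SYNP0008957768	SYNG074	8	0.998
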