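gene	gene_name	betweenness	fdr
ENSP00000227638	PANX1	72	0
ENSP00000235310	MAD2L2	72	0
ENSP00000245323	EFNB2	335	0
ENSP00000258428	REV1	72	0
ENSP00000265727	ADAM22	72	0
ENSP00000281821	EPHA4	339	0
ENSP00000293831	EIF4A1	72	0
ENSP00000302719	KCNAB3	72	0
ENSP00000312697	DMAP1	88	0
ENSP00000329797	CADM1	72	0
ENSP00000335434	WDR20	72	0
ENSP00000341138	EPB41L3	72	0
ENSP00000351697	REV3L	72	0
ENSP00000354778	CNTNAP2	72	0
ENSP00000356150	MDM4	72	0
ENSP00000357177	ARHGEF11	142	0
ENSP00000361366	SFTPD	72	0
ENSP00000369218	RBM17	72	0
ENSP00000370119	SMN2	72	0
ENSP00000245304	RAP2A	72	0.001
ENSP00000275815	EPHA1	72	0.001
ENSP00000328511	KCNA4	72	0.001
ENSP00000377446	SUCLG1	210	0.001
ENSP00000399511	TNIK	72	0.001
ENSP00000229595	ASF1A	72	0.002
ENSP00000252699	ACTN4	72	0.002
ENSP00000263208	HIRA	72	0.002
ENSP00000263923	KDR	104	0.002
ENSP00000304169	PITX2	210	0.002
ENSP00000330633	CNTN2	72	0.002
ENSP00000276072	TAF1	72	0.003
ENSP00000295600	MITF	138	0.003
ENSP00000360157	FOXD3	6	0.003
ENSP00000264010	CTCF	72	0.004
ENSP00000271628	SF3B4	75	0.004
ENSP00000350941	SRC	421	0.004
ENSP00000361125	VEGFA	164	0.004
ENSP00000226091	EFNB3	67	0.006
ENSP00000358309	EPHA7	2	0.006
ENSP00000358918	SUFU	72	0.007
ENSP00000316879	EIF4G1	72	0.011
ENSP00000260653	SIX3	2	0.012
ENSP00000352516	DNMT1	90	0.016
ENSP00000358716	DDX20	72	0.017
ENSP00000357393	EFNA3	50	0.018
ENSP00000341680	DTNBP1	66	0.02
ENSP00000344456	CTNNB1	607	0.02
ENSP00000297904	FIGF	2	0.021
ENSP00000265165	LEF1	134	0.022
ENSP00000347948	TNFRSF14	68	0.023
ENSP00000288986	NCK1	78	0.027
ENSP00000261937	FLT4	2	0.029
ENSP00000333919	BTLA	68	0.03
ENSP00000332549	GRIN2A	58	0.032
ENSP00000376765	PIAS3	4	0.033
ENSP00000361818	SDC4	1	0.035
ENSP00000386165	CEBPD	38	0.035
ENSP00000348307	SIRPA	34	0.036
ENSP00000344666	NF2	1	0.037
ENSP00000219255	PARD6A	72	0.038
ENSP00000204961	EFNB1	5	0.039
ENSP00000172229	NGFR	72	0.043
ENSP00000344115	CDH5	24	0.043
ENSP00000405041	POU5F1	6	0.045
ENSP00000360532	CDC5L	6	0.046
ENSP00000295897	ALB	72	0.047
ENSP00000340944	PTPN11	112	0.047
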