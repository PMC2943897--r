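pair_id	printed_block	role	gene	invitro_fc	tn_I	tn_II	tn_III	tn_IV	tn_V
1	concordant	L	ANGPTL1	0.09	0.20	0.21	NA	NA	NA
1	concordant	R	TEK	0.19	0.70	0.63	0.63	NA	NA
2	concordant	L	AREG	148.50	NA	NA	2.00	NA	NA
2	concordant	R	EGFR	2.42	NA	1.67	1.67	1.25	NA
3	concordant	L	BTC	9.46	NA	1.25	NA	NA	NA
3	concordant	R	EGFR	2.42	NA	1.67	1.67	1.25	NA
4	concordant	L	DTR	4.47	NA	NA	2.50	NA	NA
4	concordant	R	EGFR	2.42	NA	1.67	1.67	1.25	NA
5	concordant	L	TGFA	14.22	4.17	3.33	5.00	NA	NA
5	concordant	R	EGFR	2.42	NA	1.67	1.67	1.25	NA
6	concordant	L	FGF7	0.13	NA	NA	0.63	NA	NA
6	concordant	R	FGFR2	0.03	0.40	0.43	0.26	0.83	NA
7	concordant	L	EFNA4	36.76	NA	1.67	NA	NA	NA
7	concordant	R	EPHA4	2.59	2.22	2.00	3.33	NA	1.43
8	concordant	L	PLAU	21.22	4.35	2.50	10.00	2.50	3.33
8	concordant	R	PLAUR	4.63	NA	1.25	3.33	NA	NA
9	concordant	L	SPP1	3.52	NA	2.50	3.33	2.00	2.00
9	concordant	R	CD44	3.70	2.22	1.67	2.00	1.67	1.67
10	concordant	L	SPP1	3.52	NA	2.50	3.33	2.00	2.00
10	concordant	R	ITGA9	4.64	1.59	NA	1.67	NA	NA
11	discordant	L	CXCL12	2.59	0.20	0.45	0.29	0.42	NA
11	discordant	R	CXCR4	107.10	0.40	NA	NA	NA	NA
12	discordant	L	TNFSF10	3.55	0.40	NA	0.50	0.77	NA
12	discordant	R	TNFRSF11B	2.23	0.10	0.19	0.18	NA	NA
13	discordant	L	PGF	4.34	0.30	NA	0.40	NA	NA
13	discordant	R	NRP1	5.61	NA	0.77	NA	NA	NA
14	discordant	L	TGFB2	0.28	NA	1.25	NA	NA	NA
14	discordant	R	TGFBR1	0.48	NA	1.43	NA	NA	NA
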