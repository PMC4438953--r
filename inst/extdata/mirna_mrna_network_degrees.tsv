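side	node	degree
miRNA	hsa-miR-494	14
miRNA	hsa-miR-96	11
miRNA	hsa-miR-455-3p	8
miRNA	hsa-miR-542-3p	7
miRNA	hsa-miR-183	6
miRNA	hsa-miR-374a	6
miRNA	hsa-miR-375	5
miRNA	hsa-miR-21	4
miRNA	hsa-miR-7	4
miRNA	hsa-miR-148a	3
miRNA	hsa-miR-192	3
miRNA	hsa-miR-221	3
miRNA	hsa-miR-34b	3
miRNA	hsa-miR-490-5p	3
miRNA	hsa-let-7f	2
miRNA	hsa-miR-15b	2
miRNA	hsa-miR-424	2
miRNA	hsa-miR-454	1
miRNA	hsa-miR-98	1
gene	RUNX1T1	3
gene	AGPS	2
gene	CDK19	2
gene	ENAH	2
gene	IKZF2	2
gene	MAGI1	2
gene	MEIS1	2
gene	NEBL	2
gene	NFIA	2
gene	PAQR8	2
gene	PDCD4	2
gene	PLCXD3	2
gene	PLEKHA6	2
gene	PTGER3	2
gene	RECK	2
gene	SESN1	2
gene	SH3BGRL2	2
gene	SLC16A7	2
gene	TACC1	2
gene	ATOH8	1
gene	C18orf25	1
gene	CAPN5	1
gene	CBX3	1
gene	CCNG2	1
gene	CCRN4L	1
gene	CDK6	1
gene	CHRDL1	1
gene	CILP	1
gene	CKS1B	1
gene	CLPTM1L	1
gene	DIAPH2	1
gene	ESPL1	1
gene	FBXO45	1
gene	FCHO2	1
gene	GALNT2	1
gene	GAS7	1
gene	HLF	1
gene	IRS1	1
gene	ITGA9	1
gene	ITPR2	1
gene	KIAA0141	1
gene	KLB	1
gene	LIFR	1
gene	LYRM7	1
gene	MBNL3	1
gene	MRPS23	1
gene	MYRIP	1
gene	NADK	1
gene	NCF2	1
gene	NCOA1	1
gene	NR2F2	1
gene	NTRK3	1
gene	PER3	1
gene	PHF17	1
gene	PLAGL1	1
gene	PPFIA1	1
gene	RUFY3	1
gene	SAMD5	1
gene	SLC16A6	1
gene	SLC7A11	1
gene	SLIT3	1
gene	ST3GAL3	1
gene	TACR1	1
gene	TOR1A	1
gene	TRIOBP	1
gene	VSIG10	1
gene	WDR26	1
gene	ZNF281	1
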