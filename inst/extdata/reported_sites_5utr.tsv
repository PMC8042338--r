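gene	gene_rpkm	region	mirna_id	host_rpkm	starts	n_starts	delta_g_lo	delta_g_hi	ratio_lo	ratio_hi	length_nt
GSK3B	8.3	5UTR	ID02187.5p-miR	NA	3	1	-123	-123	89	89	23
GSK3B	8.3	5UTR	ID03229.5p-miR	NA	4	1	-123	-123	92	92	22
GSK3B	8.3	5UTR	ID01804.3p-miR	NA	5,12	2	-134	-134	91	91	23
GSK3B	8.3	5UTR	ID00756.3p-miR	NA	8	1	-123	-123	89	89	23
GSK3B	8.3	5UTR	ID01041.5p-miR	NA	8	1	-132	-132	90	90	24
GSK3B	8.3	5UTR	ID02294.5p-miR	NA	8	1	-127	-127	87	87	24
GSK3B	8.3	5UTR	ID00457.3p-miR	NA	8,11	2	-129	-123	91	95	22
GSK3B	8.3	5UTR	ID03367.5p-miR	NA	11	1	-119	-119	95	95	20
GSK3B	8.3	5UTR	ID00061.3p-miR	NA	8,11	2	-136	-125	91	98	22
GSK3B	8.3	5UTR	ID00296.3p-miR	NA	9	1	-138	-138	88	88	25
GSK3B	8.3	5UTR	ID01641.3p-miR	NA	9	1	-127	-127	86	86	24
GSK3B	8.3	5UTR	ID03151.3p-miR	NA	9,12	2	-115	-115	93	93	20
GSK3B	8.3	5UTR	ID03229.5p-miR	NA	10	1	-123	-123	92	92	22
GSK3B	8.3	5UTR	ID01702.3p-miR	NA	13	1	-140	-140	93	93	24
GSK3B	8.3	5UTR	ID02064.5p-miR	NA	10,13	2	-136	-129	90	94	23
GSK3B	8.3	5UTR	ID01873.3p-miR	NA	11	1	-123	-123	94	94	21
GSK3B	8.3	5UTR	miR-3960	NA	11,14	2	-115	-115	92	92	20
GSK3B	8.3	5UTR	ID02522.3p-miR	NA	12	1	-127	-127	91	91	23
GSK3B	8.3	5UTR	ID02499.3p-miR	NA	13	1	-119	-119	92	92	21
GSK3B	8.3	5UTR	ID02429.3p-miR	NA	14	1	-125	-125	92	92	23
GSK3B	8.3	5UTR	ID01652.3p-miR	NA	15	1	-125	-125	89	89	23
GSK3B	8.3	5UTR	ID02538.3p-miR	NA	15	1	-121	-121	90	90	22
PPARGC1A	2.5	5UTR	ID00470.5p-miR	NA	18..47	5	-110	-108	89	91	23
PPARGC1A	2.5	5UTR	miR-574-5p	1.5	20..31	5	-113	-108	89	93	23
PPARGC1A	2.5	5UTR	ID02299.5p-miR	NA	30	1	-98	-98	92	92	21
PPARGC1A	2.5	5UTR	ID02732.3p-miR	NA	36,42	2	-121	-121	89	89	23
PPARGC1A	2.5	5UTR	ID03332.3p-miR	NA	71	1	-134	-134	90	90	24
PPARGC1A	2.5	5UTR	ID01310.3p-miR	NA	135..144	4	-123	-121	92	94	22
PPARGC1A	2.5	5UTR	ID03332.3p-miR	NA	143,146	2	-140	-134	90	94	24
PPARGC1A	2.5	5UTR	ID02761.3p-miR	NA	149	1	-132	-132	89	89	24
ZFAND4	0.5	5UTR	ID03418.3p-miR	NA	109	1	-123	-123	87	87	23
ZFAND4	0.5	5UTR	ID00296.3p-miR	NA	112	1	-134	-134	85	85	25
ZFAND4	0.5	5UTR	ID03206.5p-miR	NA	114	1	-115	-115	92	92	20
ZFAND4	0.5	5UTR	ID01190.5p-miR	NA	114	1	-136	-136	89	89	24
ZFAND4	0.5	5UTR	ID00030.3p-miR	NA	114	1	-125	-125	94	94	22
ZFAND4	0.5	5UTR	ID02294.5p-miR	NA	114	1	-125	-125	86	86	24
ZFAND4	0.5	5UTR	ID01574.5p-miR	NA	116	1	-121	-121	86	86	23
ZFAND4	0.5	5UTR	ID01804.3p-miR	NA	118	1	-125	-125	86	86	23
ZFAND4	0.5	5UTR	ID01702.3p-miR	NA	118	1	-129	-129	86	86	24
ZFAND4	0.5	5UTR	ID03367.5p-miR	NA	118	1	-113	-113	90	90	20
ZFAND4	0.5	5UTR	ID03073.3p-miR	NA	128	1	-129	-129	94	94	23
CCNY	19.7	5UTR	ID01041.5p-miR	NA	1	1	-136	-136	93	93	24
CCNY	19.7	5UTR	ID01873.3p-miR	NA	1	1	-123	-123	94	94	21
CCNY	19.7	5UTR	ID00296.3p-miR	NA	4	1	-140	-140	89	89	25
CCNY	19.7	5UTR	ID01702.3p-miR	NA	4	1	-134	-134	89	89	24
CCNY	19.7	5UTR	ID01641.3p-miR	NA	4	1	-132	-132	89	89	24
CCNY	19.7	5UTR	ID01106.5p-miR	NA	7	1	-132	-132	89	89	24
CCNY	19.7	5UTR	ID01879.5p-miR	NA	8	1	-129	-129	95	95	22
CCNY	19.7	5UTR	ID02229.3p-miR	NA	9	1	-121	-121	92	92	21
CCNY	19.7	5UTR	ID02499.3p-miR	NA	9	1	-123	-123	95	95	21
CCNY	19.7	5UTR	ID03027.3p-miR	NA	11	1	-121	-121	85	85	24
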