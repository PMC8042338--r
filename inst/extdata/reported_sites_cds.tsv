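gene	gene_rpkm	region	mirna_id	host_rpkm	starts	n_starts	delta_g_lo	delta_g_hi	ratio_lo	ratio_hi	length_nt
APOE	269.2	CDS	ID03402.5p-miR	NA	758	1	-121	-121	95	95	22
APOE	269.2	CDS	ID03398.5p-miR	NA	881	1	-115	-115	93	93	20
APOE	269.2	CDS	ID03261.5p-miR	NA	883	1	-115	-115	93	93	20
FOXO1	2.5	CDS	ID03332.3p-miR	NA	655,658	2	-140	-136	91	94	24
FOXO1	2.5	CDS	ID02761.3p-miR	NA	661	1	-132	-132	89	89	24
FOXO1	2.5	CDS	ID02611.3p-miR	NA	660	1	-125	-125	91	91	22
FOXO1	2.5	CDS	ID00171.3p-miR	NA	666	1	-117	-117	93	93	20
FOXO1	2.5	CDS	ID01804.3p-miR	NA	672	1	-136	-136	93	93	23
FOXO1	2.5	CDS	ID01057.5p-miR	NA	745	1	-123	-123	91	91	23
FOXO1	2.5	CDS	ID02429.3p-miR	NA	749	1	-123	-123	91	91	23
SETD1A	4.5	CDS	miR-6824-5p	NA	2062	1	-113	-113	90	90	22
SETD1A	4.5	CDS	miR-1207-5p	0.2	2064	1	-115	-115	93	93	21
SETD1A	4.5	CDS	ID00850.3p-miR	NA	2495	1	-117	-117	90	90	22
SETD1A	4.5	CDS	ID01321.5p-miR	NA	2498	1	-113	-113	91	91	21
SETD1A	4.5	CDS	miR-762	19.1	4098	1	-125	-125	92	92	22
SETD1A	4.5	CDS	miR-6891-3p	NA	4759	1	-106	-106	93	93	21
SETD1A	4.5	CDS	ID03324.3p-miR	NA	4764,4788	2	-115	-115	90	90	22
SETD1A	4.5	CDS	ID03238.3p-miR	NA	4769	1	-117	-117	90	90	23
SETD1A	4.5	CDS	ID01545.3p-miR	NA	4776	1	-113	-113	93	93	21
SETD1A	4.5	CDS	ID02538.3p-miR	NA	4877	1	-121	-121	90	90	22
SETD1A	4.5	CDS	ID01641.3p-miR	NA	4894,4900	2	-140	-132	89	94	24
SETD1A	4.5	CDS	ID01323.3p-miR	NA	4898	1	-123	-123	91	91	22
SETD1A	4.5	CDS	miR-3960	NA	4899	1	-115	-115	92	92	20
SETD1A	4.5	CDS	ID00296.3p-miR	NA	4900	1	-140	-140	89	89	25
SETD1A	4.5	CDS	ID01702.3p-miR	NA	4900	1	-134	-134	89	89	24
SETD1A	4.5	CDS	ID01959.3p-miR	NA	4905	1	-117	-117	92	92	21
SETD1A	4.5	CDS	ID00962.3p-miR	NA	4905	1	-117	-117	89	89	23
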