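gene	gene_rpkm	region	mirna_id	host_rpkm	starts	n_starts	delta_g_lo	delta_g_hi	ratio_lo	ratio_hi	length_nt
GSK3B	8.3	3UTR	ID01030.3p-miR	NA	4705..4719	4	-113	-108	89	93	23
GSK3B	8.3	3UTR	miR-466	NA	4709..4721	6	-106	-104	89	91	23
GSK3B	8.3	3UTR	ID00436.3p-miR	NA	4713..4723	3	-104	-104	89	89	23
GSK3B	8.3	3UTR	ID01727.5p-miR	NA	4722	1	-106	-106	91	91	23
LRP10	7.8	3UTR	miR-5096	1.6	3237	1	-104	-104	92	92	21
LRP10	7.8	3UTR	ID02175.3p-miR	NA	3353	1	-110	-110	91	91	22
LRP10	7.8	3UTR	miR-5585-3p	3.6	3305	1	-115	-115	98	98	22
LRP10	7.8	3UTR	miR-1285-5p	5.3	3404	1	-102	-102	91	91	21
LRP10	7.8	3UTR	miR-619-5p	4.3	3497	1	-110	-110	91	91	22
LRP10	7.8	3UTR	miR-4452	19.7	3544	1	-108	-108	94	94	23
LRP10	7.8	3UTR	miR-5095	8.3	3788	1	-106	-106	91	91	21
LRP10	7.8	3UTR	miR-619-5p	4.3	3794	1	-115	-115	95	95	22
LRP10	7.8	3UTR	ID00913.5p-miR	NA	3814	1	-117	-117	92	92	23
PDP2	1.2	3UTR	ID00047.3p-miR	NA	3220	1	-110	-110	93	93	21
PDP2	1.2	3UTR	miR-5096	1.6	3920	1	-108	-108	96	96	21
PDP2	1.2	3UTR	miR-619-5p	4.3	3980	1	-113	-113	93	93	22
PDP2	1.2	3UTR	miR-5585-3p	3.6	3987	1	-106	-106	91	91	22
PDP2	1.2	3UTR	miR-1285-5p	5.3	4086	1	-102	-102	91	91	21
PDP2	1.2	3UTR	ID01200.3p-miR	NA	4511	1	-102	-102	91	91	21
PDP2	1.2	3UTR	miR-1273a	0.2	4639	1	-119	-119	90	90	25
PDP2	1.2	3UTR	miR-1273c	3.3	4641	1	-110	-110	91	91	22
PDP2	1.2	3UTR	miR-1273g-3p	8.3	4661	1	-106	-106	91	91	21
PDP2	1.2	3UTR	ID01360.3p-miR	NA	5493	1	-104	-104	91	91	21
PDP2	1.2	3UTR	miR-3159	NA	5861	1	-106	-106	91	91	22
PDP2	1.2	3UTR	miR-619-5p	4.3	5863	1	-113	-113	93	93	22
PDP2	1.2	3UTR	miR-619-5p	4.3	5988	1	-110	-110	91	91	22
PDP2	1.2	3UTR	miR-619-5p	4.3	6173	1	-119	-119	98	98	22
PDP2	1.2	3UTR	miR-5096	1.6	6247	1	-108	-108	96	96	21
PDP2	1.2	3UTR	miR-619-5p	4.3	6308	1	-117	-117	96	96	22
PDP2	1.2	3UTR	ID01836.5p-miR	NA	6398	1	-113	-113	90	90	23
PDP2	1.2	3UTR	miR-5096	1.6	6413	1	-102	-102	91	91	21
PPARGC1A	2.5	3UTR	miR-466	NA	3321,3337	2	-106	-106	91	91	23
PPARGC1A	2.5	3UTR	ID00436.3p-miR	NA	3323..3339	3	-108	-104	89	93	23
PPARGC1A	2.5	3UTR	ID01030.3p-miR	NA	3325	1	-115	-115	95	95	23
PPARGC1A	2.5	3UTR	ID01727.5p-miR	NA	3338	1	-104	-104	89	89	23
RBBP5	3.9	3UTR	miR-5095	8.3	3065	1	-108	-108	93	93	21
RBBP5	3.9	3UTR	miR-619-5p	4.3	3071	1	-113	-113	93	93	22
RBBP5	3.9	3UTR	miR-5096	1.6	3145	1	-106	-106	94	94	21
RBBP5	3.9	3UTR	ID03006.5p-miR	NA	4015	1	-121	-121	89	89	24
RBBP5	3.9	3UTR	miR-619-5p	4.3	4030	1	-115	-115	95	95	22
RBBP5	3.9	3UTR	miR-5096	1.6	4104	1	-106	-106	94	94	21
RBBP5	3.9	3UTR	miR-3159	NA	4163	1	-106	-106	91	91	22
RBBP5	3.9	3UTR	ID02175.3p-miR	NA	4220	1	-113	-113	93	93	22
RBBP5	3.9	3UTR	ID01237.3p-miR	NA	4271	1	-117	-117	92	92	24
SLC14A1	8.5	3UTR	miR-5095	8.3	2771	1	-110	-110	95	95	21
SLC14A1	8.5	3UTR	miR-619-5p	4.3	2777	1	-119	-119	98	98	22
SLC14A1	8.5	3UTR	miR-5096	1.6	2851	1	-102	-102	91	91	21
SLC14A1	8.5	3UTR	miR-619-5p	4.3	3215	1	-115	-115	95	95	22
SLC14A1	8.5	3UTR	ID01836.5p-miR	NA	3003	1	-113	-113	90	90	23
VSNL1	206.5	3UTR	miR-574-5p	1.5	1021..1045	13	-113	-108	89	93	23
VSNL1	206.5	3UTR	ID00470.5p-miR	NA	1023..1045	12	-108	-108	89	89	23
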