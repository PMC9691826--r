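gene	cancer	age_lo	age_hi	form	c	u	v
BRCA1	bc	0	19	constant	1	NA	NA
BRCA1	bc	20	29	loglinear	NA	3.0146	0.02412
BRCA1	bc	30	39	loglinear	NA	6.0707	-0.07775
BRCA1	bc	40	49	loglinear	NA	4.2511	-0.03226
BRCA1	bc	50	79	loglinear	NA	4.2086	-0.03141
BRCA1	eoc	0	29	constant	1	NA	NA
BRCA1	eoc	30	39	loglinear	NA	-3.55	0.1986
BRCA1	eoc	40	49	loglinear	NA	7.1776	-0.06959
BRCA1	eoc	50	79	loglinear	NA	4.5236	-0.01651
BRCA1	mbc	0	79	constant	8	NA	NA
BRCA1	prostate	0	64	constant	1.82	NA	NA
BRCA1	prostate	65	79	constant	0.84	NA	NA
BRCA1	pancreas	0	64	constant	3.10	NA	NA
BRCA1	pancreas	65	79	constant	1.54	NA	NA
BRCA2	bc	0	19	constant	1	NA	NA
BRCA2	bc	20	29	loglinear	NA	3.2153	-0.008815
BRCA2	bc	30	39	loglinear	NA	4.28945	-0.04462
BRCA2	bc	40	49	loglinear	NA	3.96865	-0.0366
BRCA2	bc	50	59	loglinear	NA	1.8169	0.006435
BRCA2	bc	60	69	loglinear	NA	-0.2606	0.04106
BRCA2	bc	70	79	constant	13.0991	NA	NA
BRCA2	eoc	0	39	constant	1	NA	NA
BRCA2	eoc	40	53	loglinear	NA	-9.708	0.2427
BRCA2	eoc	54	57	loglinear	NA	6.50334	-0.05751
BRCA2	eoc	58	69	loglinear	NA	11.3175	-0.140513
BRCA2	eoc	70	79	constant	4.4	NA	NA
BRCA2	mbc	0	79	constant	80	NA	NA
BRCA2	prostate	0	64	constant	7.33	NA	NA
BRCA2	prostate	65	79	constant	3.39	NA	NA
BRCA2	pancreas	0	64	constant	5.54	NA	NA
BRCA2	pancreas	65	79	constant	1.61	NA	NA
PALB2	bc	0	19	constant	1	NA	NA
PALB2	bc	20	24	constant	9.1	NA	NA
PALB2	bc	25	29	constant	8.97	NA	NA
PALB2	bc	30	34	constant	8.85	NA	NA
PALB2	bc	35	39	constant	8.54	NA	NA
PALB2	bc	40	44	constant	8.02	NA	NA
PALB2	bc	45	49	constant	7.31	NA	NA
PALB2	bc	50	54	constant	6.55	NA	NA
PALB2	bc	55	59	constant	5.92	NA	NA
PALB2	bc	60	64	constant	5.45	NA	NA
PALB2	bc	65	69	constant	5.1	NA	NA
PALB2	bc	70	74	constant	4.82	NA	NA
PALB2	bc	75	79	constant	4.56	NA	NA
PALB2	eoc	0	29	constant	1	NA	NA
PALB2	eoc	30	79	constant	2.91	NA	NA
PALB2	mbc	0	29	constant	1	NA	NA
PALB2	mbc	30	79	constant	7.34	NA	NA
PALB2	pancreas	0	29	constant	1	NA	NA
PALB2	pancreas	30	79	constant	2.37	NA	NA
CHEK2	bc	0	19	constant	1	NA	NA
CHEK2	bc	20	79	loglinear	NA	1.6053	-0.01483
ATM	bc	0	79	constant	2.10	NA	NA
BARD1	bc	0	79	constant	2.09	NA	NA
RAD51C	bc	0	79	constant	1.97	NA	NA
RAD51C	eoc	0	29	constant	1	NA	NA
RAD51C	eoc	30	59	loglinear	NA	-1.7974	0.07631
RAD51C	eoc	60	79	loglinear	NA	9.7592	-0.1163
RAD51D	bc	0	79	constant	1.82	NA	NA
RAD51D	eoc	0	29	constant	1	NA	NA
RAD51D	eoc	30	57	loglinear	NA	-2.88662	0.09656
RAD51D	eoc	58	79	loglinear	NA	5.99144	-0.05651
BRIP1	eoc	0	79	constant	3.41	NA	NA
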