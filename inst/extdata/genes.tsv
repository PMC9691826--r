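model	gene	allele_freq	sensitivity	dominance_rank
bc	BRCA1	0.0006394	0.89	1
bc	BRCA2	0.00102	0.96	2
bc	PALB2	0.00064	0.92	3
bc	CHEK2	0.00373	0.98	4
bc	ATM	0.0018	0.94	5
bc	BARD1	0.00043	0.89	6
bc	RAD51C	0.00035	0.78	7
bc	RAD51D	0.00035	0.86	8
eoc	BRCA1	0.0007947	0.89	1
eoc	BRCA2	0.002576	0.96	2
eoc	RAD51D	0.00035	0.86	3
eoc	RAD51C	0.00035	0.78	4
eoc	BRIP1	0.00071	0.95	5
eoc	PALB2	0.00064	0.92	6
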