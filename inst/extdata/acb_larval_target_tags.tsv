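name	tag17	egg	larva	pupa	adult
DS2	GACGCTGGTGAACACCT	0	6325	1942	1136
DS3	CTGACCGCCGCCGCGGA	0	5134	2839	550
DS5	GTTTAACAGCCATATGT	0	3281	0	0
DS6	GGGCTTCCCCTGCGCCC	8	2244	0	8
DS10	CACCCTCAGTGGACCCC	0	1239	2	0
DS12	GTGTTCGCGTGAACAAC	15	1229	29	64
DS28	AGAATAATGCAAGCTTG	0	566	0	0
DS30	ACGAGCTATCATCGCCT	0	537	0	0
DS34	CAGTACAAGCCGAACCA	0	421	2	0
DS35	ATGGTTCTTTATCCAAC	4	390	0	0
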