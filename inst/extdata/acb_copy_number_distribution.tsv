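bin	egg	larva	pupa	adult
2	22429	22416	28418	28979
3~9	28164	28837	36678	35670
10~49	13682	13802	17167	16720
50~99	2908	2646	3341	3515
100~199	1860	1594	1957	2027
200~299	664	597	635	728
300~399	318	269	369	367
400~499	205	182	219	241
500~999	383	397	446	442
1000~1999	212	238	193	236
2000~4999	101	158	146	133
5000~9999	39	59	42	35
>=10000	39	33	26	23
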