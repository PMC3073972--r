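category	egg_total	egg_unique	larva_total	larva_unique	pupa_total	pupa_unique	adult_total	adult_unique
raw	3695998	190977	3663435	191840	3704416	236104	3601481	230618
low_quality	14412	7036	14207	6990	14701	8028	14177	8094
adaptors	0	0	0	0	0	0	0	0
copynum_lt2	112937	112937	113622	113622	138439	138439	133408	133408
clean	3568649	71004	3535606	71228	3551276	89637	3453896	89116
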