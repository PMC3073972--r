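set	class_bounds	class1	class2	class3	class4	class5	n50	mean	n_sequences	total_length
contig	100,200,300,400,500	88670	17490	8431	3995	5457	211	198	124043	24499499
scaffold	100,500,1000,1500,2000	65965	10308	2403	716	433	455	334	79825	26641821
unigene	100,500,1000,1500,2000	31899	10302	2398	719	432	555	485	45750	22205852
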