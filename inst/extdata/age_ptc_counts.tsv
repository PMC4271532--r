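category	relationship	ptc_free	low	moderate	high
old	total	10580	460	74	7
young	total	764	89	32	7
dna_based	strict	329	42	18	3
dna_based	raw	589	77	30	5
rna_based	strict	76	6	0	0
rna_based	raw	91	10	0	0
de_novo	strict	84	2	2	2
de_novo	raw	84	2	2	2
dna_parent_with_ptc	strict	0	33	0	0
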