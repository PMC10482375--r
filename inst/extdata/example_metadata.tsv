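# Synthetic miniature cohort (hand-written illustration of the dialect).
genome_id	phylum	genus	species	replicon_id	replicon_type	topology	length	gc
sA1	Actinobacteria	Streptomyces	Streptomyces_sp1	sA1_chr	chromosome	linear	8100000	0.72
sA1	Actinobacteria	Streptomyces	Streptomyces_sp1	sA1_pls	plasmid	linear	250000	0.70
sA2	Actinobacteria	Streptomyces	Streptomyces_sp2	sA2_chr	chromosome	linear	7600000	0.71
rB1	Actinobacteria	Rhodococcus	Rhodococcus_sp1	rB1_chr	chromosome	circular	5400000	0.67
eC1	Proteobacteria	Escherichia	Escherichia_sp1	eC1_chr	chromosome	circular	4600000	0.51
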