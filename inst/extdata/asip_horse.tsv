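# Temporal allele counts at the ASIP coat-coloration locus in domesticated
# horses. Counts transcribed from Ludwig et al. (2009) Science 324:485
# (as reused in several later reanalyses of selection at this locus).
# years_bp: sample age in years before present; n: haplotypes genotyped;
# a: derived-allele count.
years_bp	n	a
20000	10	0
13100	22	1
3700	20	15
2800	20	12
1100	36	15
500	38	18
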