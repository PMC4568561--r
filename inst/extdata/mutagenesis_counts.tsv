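gene	target_sites	concentration	n_mutant_individuals	n_observed	printed_phenotype_rate	printed_mutation_rate	printed_mutation_types	printed_rate_consistent
Abd-B	T42	200;300	7	88	7.95	35.38	D: 3-51; I: 4-18	TRUE
Abd-B	T42	600;600	10	121	8.26	25	D: 3-66; I: 4-5; M: 40	TRUE
Abd-B	T42/T95	50/50;100	6	100	6	18.33	D: 5-59; I: 3-19	TRUE
Abd-B	T42/T95	566/416;1200	123	134	91.79	90.85	D: 3-73; I: 3-64; M: 3-29	TRUE
ebony	T2/T303	158/159;1200	5	16	31.25	66.67	D: 5-33; I: 3-10; M: 3	TRUE
ebony	T454/T6	200/150;1200	22	25	88	29.92	D: 6-62; I: 3-15; M: 3-8	TRUE
fz	T268/T283	500/500;1000	4	96	4.12	45.16	D: 3-64; I: 3-15; M: 4-5	FALSE
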