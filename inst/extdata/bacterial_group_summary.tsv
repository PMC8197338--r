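group	species_analyzed	species_with_p450s	genera_analyzed	genera_with_p450s	n_p450s	n_families	n_subfamilies	n_p450s_in_bgcs	dominant_family
Alphaproteobacteria	599	241	164	82	874	143	214	21	CYP202
Firmicutes	972	229	NA	NA	712	14	53	126	CYP107
Streptomyces	203	203	NA	NA	5460	253	698	1231	CYP107
Mycobacteria	60	60	NA	NA	1784	77	132	204	CYP125
Cyanobacteria	114	114	NA	NA	341	36	79	27	CYP110
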