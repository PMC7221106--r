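hereditary_synthetic	synthetic stand-in for a hereditary hearing-loss gene list (names match the p1 preset)	marker-01-01	marker-01-02	marker-02-01	marker-03-01	excl-01-01	excl-02-01
gwas_synthetic	synthetic stand-in for GWAS-associated hearing-loss genes (names match the p1 preset)	marker-04-01	marker-05-01	marker-06-01	excl-03-01	gene00001	gene00002
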