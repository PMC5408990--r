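individual_id	family_id	study	gene	affected	age_end	age_entry
carrier01	fam01	S1	BRCA1	1	43.2	18
carrier02	fam01	S2	BRCA1	0	61	18
carrier03	fam02	S1	BRCA1	1	38.5	18
carrier04	fam03	S2	BRCA1	0	55.1	18
carrier05	fam04	S1	BRCA1	0	47.3	18
carrier06	fam05	S2	BRCA2	1	52.8	18
carrier07	fam06	S1	BRCA2	0	70.2	18
carrier08	fam07	S2	BRCA2	1	36.4	18
carrier09	fam08	S1	BRCA2	0	44.9	18
carrier10	fam09	S2	BRCA2	0	65.5	18
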