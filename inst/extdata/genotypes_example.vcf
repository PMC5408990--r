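##fileformat=VCFv4.2
##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">
##FORMAT=<ID=DS,Number=1,Type=Float,Description="Dosage">
#CHROM	POS	ID	REF	ALT	QUAL	FILTER	INFO	FORMAT	carrier01	carrier02	carrier03
1	10177	rs000101	G	A	.	PASS	.	GT:DS	0/1:1.00	1|1:1.96	0/0:0.12
2	23456	rs000202	T	C	.	PASS	.	GT:DS	0/1:1.37	./.:.	0/0:0.00
7	88888	rs000303	C	G	.	PASS	.	GT:DS	1/1:2.00	0/1:0.95	0/1:1.02
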