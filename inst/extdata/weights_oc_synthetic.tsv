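variant_id	chrom	pos	effect_allele	other_allele	effect_allele_freq	weight	phenotype_tag
rs249764	20	4885771	C	G	0.4075	-0.0037	oc
rs135311	21	13753166	G	C	0.2785	0.0271	oc
rs626096	7	14110714	A	T	0.6076	0.0722	oc
rs463015	8	14195645	A	G	0.534	-0.0402	oc
rs538527	14	18296324	G	T	0.4995	0.0071	oc
rs734697	19	24090484	T	C	0.1477	-0.1166	oc
rs847125	17	28230699	T	G	0.7862	-0.0026	oc
rs434444	19	29509635	T	A	0.5281	-0.1931	oc
rs869695	16	35919250	C	T	0.4714	-0.0684	oc
rs841955	2	63684580	G	C	0.4742	0.1655	oc
rs414216	1	65220753	T	C	0.4756	0.1593	oc
rs166534	6	70563297	A	C	0.2304	-0.0131	oc
rs575019	11	77518720	A	T	0.1894	-0.049	oc
rs351986	21	83705851	T	A	0.1555	-0.0109	oc
rs694147	18	87126178	T	A	0.327	-0.026	oc
rs780521	17	87243242	T	A	0.1285	-0.0889	oc
rs378872	4	88286412	T	C	0.7068	-0.0908	oc
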