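variant_id	chrom	pos	effect_allele	other_allele	effect_allele_freq	weight	phenotype_tag
rs647282	18	3532136	T	A	0.5514	0.0407	er_neg_bc
rs459085	6	6762295	A	T	0.1636	-0.0672	er_neg_bc
rs807509	7	8824417	G	T	0.1566	0.1138	er_neg_bc
rs565669	2	10053278	G	A	0.5989	-0.0774	er_neg_bc
rs306929	14	10526262	G	A	0.8858	0.0079	er_neg_bc
rs493511	14	13390486	A	C	0.7194	0.0816	er_neg_bc
rs223238	1	15962287	T	A	0.3402	0.0679	er_neg_bc
rs558807	6	21159939	G	A	0.6983	0.056	er_neg_bc
rs267878	20	22633479	A	T	0.8494	0.0323	er_neg_bc
rs173287	2	22736977	T	C	0.6862	0.0293	er_neg_bc
rs861019	16	23567323	C	A	0.4197	-0.0771	er_neg_bc
rs181778	5	24187071	C	G	0.7903	0.0204	er_neg_bc
rs349419	12	24675404	A	T	0.5749	-0.0694	er_neg_bc
rs243795	7	25434956	G	C	0.5826	0.0403	er_neg_bc
rs290783	12	26214075	C	T	0.8183	-0.0212	er_neg_bc
rs587698	3	27346855	G	C	0.5838	0.1684	er_neg_bc
rs748619	21	32105211	T	C	0.6898	0.0261	er_neg_bc
rs295797	6	35149051	A	T	0.6535	-0.049	er_neg_bc
rs185822	3	35734114	T	C	0.9092	0.0437	er_neg_bc
rs693152	19	36336925	A	G	0.6878	0.0695	er_neg_bc
rs401912	16	36712307	T	A	0.1998	0.0421	er_neg_bc
rs749840	11	42783052	C	T	0.134	0.0302	er_neg_bc
rs806340	13	43992077	C	G	0.1212	-0.033	er_neg_bc
rs722327	19	44174673	C	G	0.839	-0.0219	er_neg_bc
rs460633	6	44900404	G	T	0.8201	-0.0617	er_neg_bc
rs395305	10	49053018	C	T	0.7197	0.1285	er_neg_bc
rs203720	13	50090879	T	C	0.3932	-0.0074	er_neg_bc
rs395966	14	50379989	G	A	0.3993	-0.036	er_neg_bc
rs245156	15	50904346	T	A	0.2854	0.0494	er_neg_bc
rs819805	8	51631256	A	C	0.2266	0.023	er_neg_bc
rs292539	8	54252803	A	T	0.656	0.0178	er_neg_bc
rs291779	7	57814163	T	G	0.5106	-0.0186	er_neg_bc
rs771356	15	58880055	T	C	0.645	-0.0707	er_neg_bc
rs805256	15	61396466	G	A	0.5019	-0.0922	er_neg_bc
rs733524	1	61570848	G	A	0.3082	-0.0071	er_neg_bc
rs405553	17	65095561	C	T	0.8786	0.1687	er_neg_bc
rs218330	21	69175728	G	T	0.1757	-0.1035	er_neg_bc
rs891994	13	69750897	A	G	0.5827	-0.0213	er_neg_bc
rs559966	1	71681004	T	C	0.4157	0.0279	er_neg_bc
rs745792	21	74815009	A	T	0.5046	-0.0904	er_neg_bc
rs383512	22	75629227	G	C	0.3273	-0.0334	er_neg_bc
rs454653	19	78190583	A	C	0.5173	-0.1149	er_neg_bc
rs239736	1	78192139	T	C	0.1866	-0.0107	er_neg_bc
rs404094	1	79584026	G	T	0.1986	-0.0739	er_neg_bc
rs808103	13	81540804	G	A	0.1552	0.0319	er_neg_bc
rs727817	20	83628745	T	C	0.4761	0.0694	er_neg_bc
rs282684	17	83666188	A	T	0.2252	-0.0056	er_neg_bc
rs641746	2	83927273	A	G	0.8949	-0.0301	er_neg_bc
rs522686	13	85821913	A	T	0.3455	-0.0193	er_neg_bc
rs451874	2	86180535	C	T	0.4598	0.0239	er_neg_bc
rs462163	15	86353290	C	T	0.1118	0.0218	er_neg_bc
rs705229	3	87558685	C	T	0.6602	0.057	er_neg_bc
rs682104	15	88951606	G	T	0.3321	-0.0546	er_neg_bc
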