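allele_frequency	support_mate	support_split	tsd_length	tsd_sequence	te_class	family	bp	contig	tissue	genotype	sample_id
0.598	6	2	11	AGTTAGATCGC	LINE-like	I-element	439800	chr2L	gut	ProsGFP	P07
0.408	10	3	13	CAAGATTCCGTAG	LINE-like	I-element	1226830	chr2L	gut	ProsGFP	P08
0.346	4	9	5	GATCC	LTR	rover	1514072	chr2L	gut	ProsGFP	P01
0.19	10	3	5	CACTC	LTR	copia	3708117	chr2L	gut	ProsGFP	P07
0.461	11	8	12	TCCTTTAAGATA	LINE-like	I-element	4481489	chr2L	gut	ProsGFP	P02
0.146	12	6	5	TGACT	LTR	blood	5573091	chr2L	gut	ProsGFP	P04
0.405	5	1	3	ATC	LTR	rover	7759416	chr2L	gut	ProsGFP	P07
0.577	9	6	4	TGAT	LTR	rover	10579313	chr2L	gut	ProsGFP	P01
0.2	10	8	6	TTTCAT	LTR	rover	13278665	chr2L	gut	ProsGFP	P01
0.155	5	4	3	AAA	LTR	rover	14688050	chr2L	gut	ProsGFP	P03
0.344	4	5	5	CAACG	LTR	copia	18090224	chr2L	gut	ProsGFP	P07
0.351	11	1	2	CG	LTR	blood	18652010	chr2L	gut	ProsGFP	P02
0.246	8	7	5	GCCCG	LTR	rover	19077395	chr2L	gut	ProsGFP	P01
0.588	10	1	6	AGATTA	LTR	rover	19365111	chr2L	gut	ProsGFP	P05
0.312	11	1	6	AAGTTG	TIR	hobo	4722845	chr2R	gut	ProsGFP	P02
0.324	8	9	5	AGCAA	LTR	rover	5184543	chr2R	gut	ProsGFP	P03
0.107	3	9	12	TCGAGTGGATAT	LINE-like	I-element	7799059	chr2R	gut	ProsGFP	P07
0.567	10	9	5	GGTTG	LTR	rover	8503565	chr2R	gut	ProsGFP	P02
0.195	12	1	3	ACG	LTR	rover	12066433	chr2R	gut	ProsGFP	P04
0.396	7	3	8	ACCTTAAC	TIR	hobo	13127926	chr2R	gut	ProsGFP	P03
0.311	6	2	5	CGAGC	LTR	copia	13676232	chr2R	gut	ProsGFP	P06
0.333	12	9	8	TCTACCAG	TIR	hobo	14353629	chr2R	gut	ProsGFP	P05
0.217	6	7	5	GCACG	LTR	copia	15521988	chr2R	gut	ProsGFP	P06
0.358	5	5	12	ACCGTGCACATC	LINE-like	I-element	15977095	chr2R	gut	ProsGFP	P05
0.592	3	1	6	GTTCTT	LTR	rover	1892412	chr3L	gut	ProsGFP	P03
0.48	12	9	5	AATGA	LTR	copia	2009016	chr3L	gut	ProsGFP	P05
0.149	9	7	6	ATTGTG	LTR	copia	2471496	chr3L	gut	ProsGFP	P02
0.553	7	7	6	AGGCTG	LTR	rover	4180734	chr3L	gut	ProsGFP	P08
0.173	7	1	8	TATGGAAT	FB	FB4	4321266	chr3L	gut	ProsGFP	P05
0.579	7	2	4	TCCC	LTR	rover	4830529	chr3L	gut	ProsGFP	P02
0.539	2	9	3	ACT	LTR	rover	8955228	chr3L	gut	ProsGFP	P01
0.479	12	8	2	GG	LTR	blood	9588282	chr3L	gut	ProsGFP	P03
0.267	10	1	2	GG	LTR	rover	9715090	chr3L	gut	ProsGFP	P05
0.551	2	4	3	ACA	LTR	rover	10035372	chr3L	gut	ProsGFP	P06
0.342	8	8	6	TAAGCC	LTR	copia	10726074	chr3L	gut	ProsGFP	P02
0.073	11	5	5	TAGGC	LTR	rover	10934785	chr3L	gut	ProsGFP	P03
0.244	11	5	5	CCTGG	LTR	rover	12686312	chr3L	gut	ProsGFP	P02
0.181	10	9	6	GTGACC	LTR	rover	13900638	chr3L	gut	ProsGFP	P01
0.187	6	5	13	CACACCCGCCGGA	LINE-like	I-element	16344699	chr3L	gut	ProsGFP	P04
0.372	12	8	4	ATCC	LTR	copia	16694627	chr3L	gut	ProsGFP	P03
0.243	3	3	5	GGGCA	LTR	rover	3278073	chr3R	gut	ProsGFP	P01
0.179	12	5	5	ATAGT	LTR	copia	5454303	chr3R	gut	ProsGFP	P01
0.447	11	5	6	AACGTC	LTR	rover	6945925	chr3R	gut	ProsGFP	P06
0.076	2	1	4	GCAC	LTR	rover	7080485	chr3R	gut	ProsGFP	P04
0.084	5	5	6	ACGCTT	LTR	rover	7389371	chr3R	gut	ProsGFP	P03
0.596	6	8	6	AATCCA	LTR	rover	7722721	chr3R	gut	ProsGFP	P01
0.507	1	6	6	GTCGTC	LTR	copia	8126664	chr3R	gut	ProsGFP	P04
0.081	8	2	4	TGTT	LTR	blood	8510287	chr3R	gut	ProsGFP	P06
0.197	4	1	4	CTTT	LTR	blood	13047530	chr3R	gut	ProsGFP	P04
0.324	4	9	5	AGTCA	LTR	rover	18114212	chr3R	gut	ProsGFP	P05
0.369	7	6	13	TCGCAGTGGGGGG	LINE-like	I-element	715235	chrX	gut	ProsGFP	P08
0.447	11	7	4	CATG	LTR	copia	4013740	chrX	gut	ProsGFP	P04
0.102	7	8	12	TGTGGTTACTAT	LINE-like	I-element	6600963	chrX	gut	ProsGFP	P06
0.547	9	9	5	GCTAC	LTR	rover	7760832	chrX	gut	ProsGFP	P03
0.396	11	3	5	TGTTG	LTR	rover	9734063	chrX	gut	ProsGFP	P06
0.086	7	7	6	CGCTTC	LTR	copia	13729850	chrX	gut	ProsGFP	P02
0.388	11	8	5	TCCAA	LTR	rover	16895587	chrX	gut	ProsGFP	P06
0.355	1	3	5	CCCGA	LTR	rover	17293328	chrX	gut	ProsGFP	P08
0.259	3	1	5	CGCAG	LTR	rover	17391763	chrX	gut	ProsGFP	P01
0.548	8	8	4	AGGA	LTR	blood	17684241	chrX	gut	ProsGFP	P07
0.234	2	2	7	CGCGTTG	FB	FB4	17893333	chrX	gut	ProsGFP	P05
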