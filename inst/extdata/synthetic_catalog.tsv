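sample_id	genotype	tissue	chrom	position	te_family	te_class	tsd_sequence	tsd_length	support_split	support_mate	allele_frequency
P07	ProsGFP	gut	chr2L	439800	I-element	LINE-like	AGTTAGATCGC	11	2	6	0.598
P08	ProsGFP	gut	chr2L	1226830	I-element	LINE-like	CAAGATTCCGTAG	13	3	10	0.408
P01	ProsGFP	gut	chr2L	1514072	rover	LTR	GATCC	5	9	4	0.346
P07	ProsGFP	gut	chr2L	3708117	copia	LTR	CACTC	5	3	10	0.19
P02	ProsGFP	gut	chr2L	4481489	I-element	LINE-like	TCCTTTAAGATA	12	8	11	0.461
P04	ProsGFP	gut	chr2L	5573091	blood	LTR	TGACT	5	6	12	0.146
P07	ProsGFP	gut	chr2L	7759416	rover	LTR	ATC	3	1	5	0.405
P01	ProsGFP	gut	chr2L	10579313	rover	LTR	TGAT	4	6	9	0.577
P01	ProsGFP	gut	chr2L	13278665	rover	LTR	TTTCAT	6	8	10	0.2
P03	ProsGFP	gut	chr2L	14688050	rover	LTR	AAA	3	4	5	0.155
P07	ProsGFP	gut	chr2L	18090224	copia	LTR	CAACG	5	5	4	0.344
P02	ProsGFP	gut	chr2L	18652010	blood	LTR	CG	2	1	11	0.351
P01	ProsGFP	gut	chr2L	19077395	rover	LTR	GCCCG	5	7	8	0.246
P05	ProsGFP	gut	chr2L	19365111	rover	LTR	AGATTA	6	1	10	0.588
P02	ProsGFP	gut	chr2R	4722845	hobo	TIR	AAGTTG	6	1	11	0.312
P03	ProsGFP	gut	chr2R	5184543	rover	LTR	AGCAA	5	9	8	0.324
P07	ProsGFP	gut	chr2R	7799059	I-element	LINE-like	TCGAGTGGATAT	12	9	3	0.107
P02	ProsGFP	gut	chr2R	8503565	rover	LTR	GGTTG	5	9	10	0.567
P04	ProsGFP	gut	chr2R	12066433	rover	LTR	ACG	3	1	12	0.195
P03	ProsGFP	gut	chr2R	13127926	hobo	TIR	ACCTTAAC	8	3	7	0.396
P06	ProsGFP	gut	chr2R	13676232	copia	LTR	CGAGC	5	2	6	0.311
P05	ProsGFP	gut	chr2R	14353629	hobo	TIR	TCTACCAG	8	9	12	0.333
P06	ProsGFP	gut	chr2R	15521988	copia	LTR	GCACG	5	7	6	0.217
P05	ProsGFP	gut	chr2R	15977095	I-element	LINE-like	ACCGTGCACATC	12	5	5	0.358
P03	ProsGFP	gut	chr3L	1892412	rover	LTR	GTTCTT	6	1	3	0.592
P05	ProsGFP	gut	chr3L	2009016	copia	LTR	AATGA	5	9	12	0.48
P02	ProsGFP	gut	chr3L	2471496	copia	LTR	ATTGTG	6	7	9	0.149
P08	ProsGFP	gut	chr3L	4180734	rover	LTR	AGGCTG	6	7	7	0.553
P05	ProsGFP	gut	chr3L	4321266	FB4	FB	TATGGAAT	8	1	7	0.173
P02	ProsGFP	gut	chr3L	4830529	rover	LTR	TCCC	4	2	7	0.579
P01	ProsGFP	gut	chr3L	8955228	rover	LTR	ACT	3	9	2	0.539
P03	ProsGFP	gut	chr3L	9588282	blood	LTR	GG	2	8	12	0.479
P05	ProsGFP	gut	chr3L	9715090	rover	LTR	GG	2	1	10	0.267
P06	ProsGFP	gut	chr3L	10035372	rover	LTR	ACA	3	4	2	0.551
P02	ProsGFP	gut	chr3L	10726074	copia	LTR	TAAGCC	6	8	8	0.342
P03	ProsGFP	gut	chr3L	10934785	rover	LTR	TAGGC	5	5	11	0.073
P02	ProsGFP	gut	chr3L	12686312	rover	LTR	CCTGG	5	5	11	0.244
P01	ProsGFP	gut	chr3L	13900638	rover	LTR	GTGACC	6	9	10	0.181
P04	ProsGFP	gut	chr3L	16344699	I-element	LINE-like	CACACCCGCCGGA	13	5	6	0.187
P03	ProsGFP	gut	chr3L	16694627	copia	LTR	ATCC	4	8	12	0.372
P01	ProsGFP	gut	chr3R	3278073	rover	LTR	GGGCA	5	3	3	0.243
P01	ProsGFP	gut	chr3R	5454303	copia	LTR	ATAGT	5	5	12	0.179
P06	ProsGFP	gut	chr3R	6945925	rover	LTR	AACGTC	6	5	11	0.447
P04	ProsGFP	gut	chr3R	7080485	rover	LTR	GCAC	4	1	2	0.076
P03	ProsGFP	gut	chr3R	7389371	rover	LTR	ACGCTT	6	5	5	0.084
P01	ProsGFP	gut	chr3R	7722721	rover	LTR	AATCCA	6	8	6	0.596
P04	ProsGFP	gut	chr3R	8126664	copia	LTR	GTCGTC	6	6	1	0.507
P06	ProsGFP	gut	chr3R	8510287	blood	LTR	TGTT	4	2	8	0.081
P04	ProsGFP	gut	chr3R	13047530	blood	LTR	CTTT	4	1	4	0.197
P05	ProsGFP	gut	chr3R	18114212	rover	LTR	AGTCA	5	9	4	0.324
P08	ProsGFP	gut	chrX	715235	I-element	LINE-like	TCGCAGTGGGGGG	13	6	7	0.369
P04	ProsGFP	gut	chrX	4013740	copia	LTR	CATG	4	7	11	0.447
P06	ProsGFP	gut	chrX	6600963	I-element	LINE-like	TGTGGTTACTAT	12	8	7	0.102
P03	ProsGFP	gut	chrX	7760832	rover	LTR	GCTAC	5	9	9	0.547
P06	ProsGFP	gut	chrX	9734063	rover	LTR	TGTTG	5	3	11	0.396
P02	ProsGFP	gut	chrX	13729850	copia	LTR	CGCTTC	6	7	7	0.086
P06	ProsGFP	gut	chrX	16895587	rover	LTR	TCCAA	5	8	11	0.388
P08	ProsGFP	gut	chrX	17293328	rover	LTR	CCCGA	5	3	1	0.355
P01	ProsGFP	gut	chrX	17391763	rover	LTR	CGCAG	5	1	3	0.259
P07	ProsGFP	gut	chrX	17684241	blood	LTR	AGGA	4	8	8	0.548
P05	ProsGFP	gut	chrX	17893333	FB4	FB	CGCGTTG	7	2	2	0.234
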