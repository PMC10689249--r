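SNP	CHR	BP	A1	A2	BETA	SE	EAF
rs1	1	100000	A	G	0.06887304104576128	0.035774669039775484	0.10008727142788425
rs2	2	200000	A	C	0.04029433263896566	0.03445639666983748	0.11175209417068092
rs3	3	300000	T	G	0.10732939033811095	0.03226225169764725	0.12342378867945274
rs4	4	400000	T	C	0.07825698053179175	0.031299836415605034	0.13597850511602977
rs5	5	500000	A	G	0.1735120459600745	0.029315413205912386	0.14841640153102945
rs6	6	600000	A	C	0.12997290488284463	0.028903533988916593	0.1593425094314988
rs7	7	700000	T	G	0.12335441173926312	0.02815912888567574	0.1715364581543811
rs8	8	800000	T	C	0.13312233142933066	0.027433498202264782	0.18268933433203
rs9	9	900000	A	G	0.1436582400450169	0.02673761666774408	0.19471148890553383
rs10	10	1000000	A	C	0.14831226449451518	0.026154876747718804	0.20680236113878905
rs11	11	1100000	T	G	0.14992943818763727	0.025655441273134127	0.2188348233612556
rs12	12	1200000	T	C	0.1735850415682932	0.025078050613626605	0.23101502855218764
rs13	13	1300000	A	G	0.2404495396706799	0.02437115634655652	0.2426042618692578
rs14	14	1400000	A	C	0.2047346585394083	0.024238048299075034	0.2536334462593542
rs15	15	1500000	T	G	0.2260848126987307	0.02382459287005373	0.2664252386220735
rs16	16	1600000	T	C	0.2530386765831882	0.02349604960623454	0.2765817087333274
rs17	17	1700000	A	G	0.27162556552858613	0.023183566533452004	0.28961057702218895
rs18	18	1800000	A	C	0.2601725395855211	0.023019046050770896	0.3017014492554441
rs19	19	1900000	T	G	0.2561666178310672	0.02284733961824439	0.3140225256488665
rs20	20	2000000	T	C	0.31328805117258013	0.022563470681190034	0.32531627302900573
rs21	21	2100000	A	G	0.307595450454708	0.02244788046337677	0.33772324649711727
rs22	22	2200000	A	C	0.3317405577999724	0.02231518167164231	0.3481855101942648
rs23	1	2300000	T	G	0.3457739857802149	0.022207266254298197	0.3612109426001388
rs24	2	2400000	T	C	0.33572882363116097	0.022150190568666808	0.37409893968651003
rs25	3	2500000	A	G	0.3541744093664246	0.02209547062884288	0.38405956446747247
rs26	4	2600000	A	C	0.35440824119839165	0.022060754877512426	0.3974904310658796
rs27	5	2700000	T	G	0.37989026572735796	0.02204371955102992	0.40900407495722324
rs28	6	2800000	T	C	0.3610928698182486	0.02204383066813236	0.4216584320004398
rs29	7	2900000	A	G	0.3944635574065601	0.022070866034305508	0.4321997210063014
rs30	8	3000000	A	C	0.41432281173574115	0.022117118230841788	0.4430639830129945
rs31	9	3100000	T	G	0.4223937254057574	0.022179522842504032	0.45571834005621104
rs32	10	3200000	T	C	0.4394775470349082	0.0222634580526901	0.46659290971186684
rs33	11	3300000	A	G	0.4300147592267743	0.022332433743625413	0.47921977969118285
rs34	12	3400000	A	C	0.4446493070331706	0.022474622073896052	0.4935542835153206
rs35	13	3500000	T	G	0.47825539459424826	0.022641664237172954	0.5029308081883963
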