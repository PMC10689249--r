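SNP	CHR	BP	A1	A2	BETA	SE	EAF
rs1	1	100000	A	G	0.09531017980432493	0.02	0.1
rs2	2	200000	A	C	0.11289362100301967	0.02	0.11176470588235295
rs3	3	300000	T	G	0.1304770622017144	0.02	0.12352941176470589
rs4	4	400000	T	C	0.14806050340040916	0.02	0.13529411764705884
rs5	5	500000	A	G	0.16564394459910387	0.02	0.14705882352941177
rs6	6	600000	A	C	0.18322738579779843	0.02	0.1588235294117647
rs7	7	700000	T	G	0.2008108269964932	0.02	0.17058823529411765
rs8	8	800000	T	C	0.21839426819518798	0.02	0.1823529411764706
rs9	9	900000	A	G	0.2359777093938827	0.02	0.19411764705882353
rs10	10	1000000	A	C	0.2535611505925773	0.02	0.20588235294117646
rs11	11	1100000	T	G	0.27114459179127215	0.02	0.21764705882352942
rs12	12	1200000	T	C	0.2887280329899668	0.02	0.22941176470588234
rs13	13	1300000	A	G	0.30631147418866156	0.02	0.2411764705882353
rs14	14	1400000	A	C	0.3238949153873562	0.02	0.2529411764705882
rs15	15	1500000	T	G	0.3414783565860509	0.02	0.2647058823529412
rs16	16	1600000	T	C	0.3590617977847457	0.02	0.27647058823529413
rs17	17	1700000	A	G	0.3766452389834404	0.02	0.28823529411764703
rs18	18	1800000	A	C	0.39422868018213514	0.02	0.30000000000000004
rs19	19	1900000	T	G	0.41181212138082984	0.02	0.31176470588235294
rs20	20	2000000	T	C	0.4293955625795246	0.02	0.32352941176470584
rs21	21	2100000	A	G	0.44697900377821936	0.02	0.33529411764705885
rs22	22	2200000	A	C	0.46456244497691396	0.02	0.34705882352941175
rs23	1	2300000	T	G	0.48214588617560883	0.02	0.35882352941176465
rs24	2	2400000	T	C	0.4997293273743035	0.02	0.37058823529411766
rs25	3	2500000	A	G	0.5173127685729981	0.02	0.38235294117647056
rs26	4	2600000	A	C	0.534896209771693	0.02	0.3941176470588236
rs27	5	2700000	T	G	0.5524796509703875	0.02	0.40588235294117647
rs28	6	2800000	T	C	0.5700630921690824	0.02	0.41764705882352937
rs29	7	2900000	A	G	0.5876465333677771	0.02	0.4294117647058824
rs30	8	3000000	A	C	0.6052299745664718	0.02	0.4411764705882353
rs31	9	3100000	T	G	0.6228134157651666	0.02	0.4529411764705882
rs32	10	3200000	T	C	0.6403968569638612	0.02	0.4647058823529412
rs33	11	3300000	A	G	0.657980298162556	0.02	0.4764705882352941
rs34	12	3400000	A	C	0.6755637393612506	0.02	0.4882352941176471
rs35	13	3500000	T	G	0.6931471805599453	0.02	0.5
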