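# Toy synthetic haplogroup marker panel for examples and demonstrations.
haplogroup	parent	marker	position	ancestral	derived	key	ref
HGA	Y-Adam	M101	1001	A	G	1	A
HGA	Y-Adam	M102	1002	A	C	1	A
HGA	Y-Adam	M103	1003	A	T	0	T
HGB	Y-Adam	M201	2001	G	C	1	G
HGB	Y-Adam	M202	2002	T	G	1	T
HGB	Y-Adam	M203	2003	C	T	1	C
HGAa	HGA	M301	3001	C	G	1	C
HGAa	HGA	M302	3002	C	A	0	C
HGAa	HGA	M303	3003	C	A	0	A
HGAb	HGA	M401	4001	T	C	1	C
HGAb	HGA	M402	4002	G	A	1	A
HGAb	HGA	M403	4003	G	C	1	G
HGBa	HGB	M501	5001	A	C	1	A
HGBa	HGB	M502	5002	T	A	0	T
HGBa	HGB	M503	5003	A	G	0	G
HGBb	HGB	M601	6001	C	A	1	C
HGBb	HGB	M602	6002	C	T	1	C
HGBb	HGB	M603	6003	A	C	1	A
HGAaa	HGAa	M701	7001	A	C	1	A
HGAaa	HGAa	M702	7002	G	A	0	G
HGAaa	HGAa	M703	7003	G	T	0	G
HGAab	HGAa	M801	8001	T	G	1	T
HGAab	HGAa	M802	8002	A	C	1	A
HGAab	HGAa	M803	8003	G	C	0	G
HGAba	HGAb	M901	9001	G	C	1	G
HGAba	HGAb	M902	9002	C	A	1	C
HGAba	HGAb	M903	9003	T	G	1	T
HGAbb	HGAb	M1001	10001	A	T	1	A
HGAbb	HGAb	M1002	10002	A	C	1	A
HGAbb	HGAb	M1003	10003	G	A	0	G
HGBaa	HGBa	M1101	11001	C	G	1	G
HGBaa	HGBa	M1102	11002	T	A	1	T
HGBaa	HGBa	M1103	11003	G	T	1	G
HGBab	HGBa	M1201	12001	C	A	1	C
HGBab	HGBa	M1202	12002	T	C	1	T
HGBab	HGBa	M1203	12003	C	A	0	C
HGBba	HGBb	M1301	13001	A	C	1	A
HGBba	HGBb	M1302	13002	A	C	1	A
HGBba	HGBb	M1303	13003	A	C	0	A
HGBbb	HGBb	M1401	14001	T	G	1	T
HGBbb	HGBb	M1402	14002	T	C	0	T
HGBbb	HGBb	M1403	14003	A	G	1	G
HGAaaa	HGAaa	M1501	15001	C	G	1	C
HGAaaa	HGAaa	M1502	15002	A	G	1	A
HGAaaa	HGAaa	M1503	15003	G	A	0	G
HGAaab	HGAaa	M1601	16001	T	C	1	C
HGAaab	HGAaa	M1602	16002	T	A	0	T
HGAaab	HGAaa	M1603	16003	A	T	1	A
HGAaba	HGAab	M1701	17001	G	A	1	G
HGAaba	HGAab	M1702	17002	T	G	0	T
HGAaba	HGAab	M1703	17003	A	T	1	A
HGAabb	HGAab	M1801	18001	A	T	1	A
HGAabb	HGAab	M1802	18002	A	C	0	A
HGAabb	HGAab	M1803	18003	T	G	1	T
HGAbaa	HGAba	M1901	19001	G	C	1	G
HGAbaa	HGAba	M1902	19002	A	T	0	A
HGAbaa	HGAba	M1903	19003	C	T	1	C
HGAbab	HGAba	M2001	20001	C	T	1	C
HGAbab	HGAba	M2002	20002	T	C	1	T
HGAbab	HGAba	M2003	20003	C	A	0	C
HGAbba	HGAbb	M2101	21001	T	A	1	T
HGAbba	HGAbb	M2102	21002	C	G	1	C
HGAbba	HGAbb	M2103	21003	C	G	0	C
HGAbbb	HGAbb	M2201	22001	G	A	1	G
HGAbbb	HGAbb	M2202	22002	A	T	1	A
HGAbbb	HGAbb	M2203	22003	T	G	0	T
HGBaaa	HGBaa	M2301	23001	G	A	1	G
HGBaaa	HGBaa	M2302	23002	A	C	1	A
HGBaaa	HGBaa	M2303	23003	G	C	0	G
HGBaab	HGBaa	M2401	24001	C	G	1	C
HGBaab	HGBaa	M2402	24002	T	A	1	T
HGBaab	HGBaa	M2403	24003	T	A	0	T
HGBaba	HGBab	M2501	25001	C	T	1	C
HGBaba	HGBab	M2502	25002	T	G	1	T
HGBaba	HGBab	M2503	25003	C	A	0	C
HGBabb	HGBab	M2601	26001	C	G	1	C
HGBabb	HGBab	M2602	26002	G	T	0	G
HGBabb	HGBab	M2603	26003	A	C	0	A
HGBbaa	HGBba	M2701	27001	T	G	1	T
HGBbaa	HGBba	M2702	27002	G	C	1	G
HGBbaa	HGBba	M2703	27003	A	C	1	A
HGBbab	HGBba	M2801	28001	T	A	1	T
HGBbab	HGBba	M2802	28002	T	G	0	T
HGBbab	HGBba	M2803	28003	A	T	0	A
HGBbba	HGBbb	M2901	29001	T	C	1	C
HGBbba	HGBbb	M2902	29002	T	C	1	T
HGBbba	HGBbb	M2903	29003	A	T	0	A
HGBbbb	HGBbb	M3001	30001	C	T	1	C
HGBbbb	HGBbb	M3002	30002	C	G	1	C
HGBbbb	HGBbb	M3003	30003	T	C	0	T
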