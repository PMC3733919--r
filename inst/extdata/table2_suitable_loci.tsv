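chromosome	species	marker	size_bp	predicted
1U	umbellulata	X1B	224	0
1U	umbellulata	X2B	162	0
1Ub	biuncialis	X1B	226	0
1Ub	biuncialis	X2B	162	0
1Ub	biuncialis	Xtr248	208	0
1Ug	geniculata	X1B	226	0
1Ug	geniculata	X2B	162	0
2U	umbellulata	X2N	558	1
2U	umbellulata	X2P	292	1
2U	umbellulata	Xtr146	303	0
2U	umbellulata	Xtr451	192	0
2Ub	biuncialis	X2N	558	1
2Ub	biuncialis	Xtr146	303	1
2Ub	biuncialis	Xtr451	262	1
2Ug	geniculata	X2N	558	0
2Ug	geniculata	X2P	292	0
2Ug	geniculata	Xtr146	303	0
2Ug	geniculata	Xtr451	262	0
3U	umbellulata	X3J	205	0
3U	umbellulata	Xtr62	180	0
3U	umbellulata	Xtr63	545	0
3U	umbellulata	Xtr80	429	0
3U	umbellulata	Xtr83	360	0
3Ub	biuncialis	X3J	205	0
3Ub	biuncialis	Xtr62	180	0
3Ub	biuncialis	Xtr63	545	0
3Ub	biuncialis	Xtr77	364	0
3Ub	biuncialis	Xtr80	429	0
3Ub	biuncialis	Xtr83	360	0
3Ug	geniculata	X3J	205	0
3Ug	geniculata	Xtr62	180	0
3Ug	geniculata	Xtr63	545	0
3Ug	geniculata	Xtr80	429	0
3Ug	geniculata	Xtr83	360	0
4U	umbellulata	X6J	236	1
4U	umbellulata	Xtr72	179	0
4U	umbellulata	Xtr76	179	0
4U	umbellulata	Xtr92	231	0
4U	umbellulata	Xtr102	318	0
4U	umbellulata	Xtr103	270	0
4Ub	biuncialis	X6J	236	1
4Ub	biuncialis	Xtr72	179	1
4Ub	biuncialis	Xtr76	179	1
4Ub	biuncialis	Xtr92	231	1
4Ub	biuncialis	Xtr103	270	1
4Ug	geniculata	X6J	236	0
4Ug	geniculata	Xtr72	179	0
4Ug	geniculata	Xtr76	179	0
4Ug	geniculata	Xtr92	231	0
4Ug	geniculata	Xtr102	318	0
4Ug	geniculata	Xtr103	270	0
4Ug	geniculata	Xtr129	300	0
5U	umbellulata	X5I	270	1
5U	umbellulata	X5Q	311	1
5U	umbellulata	Xtr128	214	0
5U	umbellulata	Xtr131	470	0
5U	umbellulata	Xtr248	208	1
5Ub	biuncialis	X5I	270	1
5Ub	biuncialis	X5Q	311	1
5Ub	biuncialis	Xtr128	214	1
5Ub	biuncialis	Xtr131	470	1
5Ug	geniculata	X5I	270	0
5Ug	geniculata	X5M	199	0
5Ug	geniculata	X5Q	311	0
5Ug	geniculata	X5S	443	0
5Ug	geniculata	Xtr128	214	0
5Ug	geniculata	Xtr131	470	0
5Ug	geniculata	Xtr248	208	0
6U	umbellulata	X2I	226	0
6U	umbellulata	X4C	385	0
6U	umbellulata	X4G	239	0
6U	umbellulata	X6A	250	0
6U	umbellulata	Xtr77	363	0
6U	umbellulata	Xtr90	290	0
6U	umbellulata	Xtr91	287	0
6U	umbellulata	Xtr400	127	0
6Ub	biuncialis	X2U	351	0
6Ub	biuncialis	X2I	230	0
6Ub	biuncialis	X4C	385	0
6Ub	biuncialis	X6A	250	0
6Ub	biuncialis	Xtr91	287	0
6Ug	geniculata	X4C	385	1
6Ug	geniculata	Xtr90	290	1
6Ug	geniculata	Xtr91	287	1
7U	umbellulata	X3B	234	1
7U	umbellulata	X7C	327	1
7U	umbellulata	X7I	248	0
7U	umbellulata	Xtr4	266	0
7Ub	biuncialis	X3B	234	1
7Ub	biuncialis	X7C	327	1
7Ub	biuncialis	X7I	248	1
7Ub	biuncialis	Xtr4	266	1
7Ug	geniculata	X3B	234	0
7Ug	geniculata	X6A	277	0
7Ug	geniculata	X7C	327	0
7Ug	geniculata	Xtr4	271	0
7Ug	geniculata	Xtr4	281	0
1M	comosa	X2B	163	1
1Mb	biuncialis	X2B	163	1
1Mg	geniculata	X1J	207	0
1Mg	geniculata	X2B	163	0
2M	comosa	X1J	228	1
2M	comosa	Xtr146	381	0
2Mb	biuncialis	X1J	228	1
2Mb	biuncialis	X2R	267	1
2Mb	biuncialis	Xtr72	168	0
2Mb	biuncialis	Xtr76	168	0
2Mb	biuncialis	Xtr131	356	0
2Mb	biuncialis	Xtr134	250	0
2Mg	geniculata	X1J	228	0
2Mg	geniculata	X2I	230	0
2Mg	geniculata	X2R	267	0
3M	comosa	Xtr62	178	0
3M	comosa	Xtr63	444	0
3M	comosa	Xtr67	351	0
3M	comosa	Xtr73	473	0
3M	comosa	Xtr80	487	0
3M	comosa	Xtr83	356	0
3M	comosa	Xtr85	226	1
3Mb	biuncialis	Xtr62	178	1
3Mb	biuncialis	Xtr63	444	1
3Mb	biuncialis	Xtr76	168	0
3Mb	biuncialis	Xtr72	168	0
3Mb	biuncialis	Xtr80	487	1
3Mb	biuncialis	Xtr83	356	1
3Mb	biuncialis	Xtr85	226	0
3Mb	biuncialis	Xtr131	356	0
3Mb	biuncialis	Xtr134	250	0
3Mb	biuncialis	Xtr471	263	0
3Mg	geniculata	Xtr62	178	1
3Mg	geniculata	Xtr63	444	1
3Mg	geniculata	Xtr80	487	1
3Mg	geniculata	Xtr83	356	1
3Mg	geniculata	Xtr85	226	1
3Mg	geniculata	Xtr146	381	0
4M	comosa	Xtr88	407	0
4Mb	biuncialis	Xtr88	407	1
4Mg	geniculata	Xtr88	407	1
5M	comosa	X5Q	311	1
5M	comosa	Xtr128	212	0
5M	comosa	Xtr471	209	0
5M	comosa	Xtr764	214	0
5Mb	biuncialis	X5Q	311	1
5Mb	biuncialis	Xtr471	209	1
5Mb	biuncialis	Xtr764	214	1
5Mg	geniculata	X5A	245	0
5Mg	geniculata	X5Q	311	0
5Mg	geniculata	Xtr128	210	0
5Mg	geniculata	Xtr471	209	1
5Mg	geniculata	Xtr764	214	0
6M	comosa	X6J	236	1
6M	comosa	Xtr93	477	0
6M	comosa	Xtr103	261	0
6M	comosa	Xtr104	406	0
6M	comosa	Xtr112	390	0
6Mb	biuncialis	X6J	236	1
6Mb	biuncialis	Xtr103	261	1
6Mg	geniculata	X6J	236	0
6Mg	geniculata	Xtr93	475	0
6Mg	geniculata	Xtr103	261	0
6Mg	geniculata	Xtr104	406	0
7M	comosa	X7C	328	1
7M	comosa	X7I	249	0
7M	comosa	X7I	312	0
7Mb	biuncialis	X6A	262	0
7Mb	biuncialis	X7C	328	0
7Mb	biuncialis	X7I	249	0
7Mb	biuncialis	X7I	312	0
7Mg	geniculata	X6A	250	0
7Mg	geniculata	X7C	328	1
7Mg	geniculata	X7I	249	0
7Mg	geniculata	X7I	312	0
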