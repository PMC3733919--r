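genome	marker	species	chromosomes
U	X6N	umbellulata	1U/3U
U	X6N	biuncialis	1Ub/3Ub
U	X6N	geniculata	1Ug/2Ug/7Ug
U	Xtr76	umbellulata	3U/4U
U	Xtr76	geniculata	3Ug/4Ug
U	X7T	geniculata	3Ug/4Ug
U	Xtr61	umbellulata	4U/7U
U	Xtr61	geniculata	4Ug/7Ug
U	X6A	umbellulata	6U/7U
U	X6A	biuncialis	6Ub/7Ub
U	X5M	geniculata	4Ug/5Ug
M	X1J	geniculata	1Mg/2Mg
M	X6N	biuncialis	2Mb/3Mb/7Mb
M	X6N	geniculata	1Mg/2Mg/6Mg
M	Xtr150	biuncialis	2Mb/7Mb
M	Xtr150	geniculata	2Mg/7Mg
M	X7L	comosa	4M/7M
M	X7I	comosa	7M/7M
M	X7I	biuncialis	7Mb/7Mb
M	X7I	geniculata	7Mg/7Mg
M	X4E	biuncialis	2Mb/3Mb
M	X4G	biuncialis	2Mb/3Mb
M	X4I	biuncialis	2Mb/3Mb
M	X4O	biuncialis	2Mb/3Mb
M	X4Q	biuncialis	2Mb/3Mb
M	X4S	biuncialis	2Mb/3Mb
M	Xtr72	biuncialis	2Mb/3Mb
M	Xtr76	biuncialis	2Mb/3Mb
M	Xtr29	biuncialis	2Mb/3Mb
M	Xtr131	biuncialis	2Mb/3Mb
M	Xtr134	biuncialis	2Mb/3Mb
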