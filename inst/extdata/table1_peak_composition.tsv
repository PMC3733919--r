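species	peak	chromosome	percent
umbellulata	I	1U	98.9
umbellulata	II	1U	25.8
umbellulata	III	1U	4.32
umbellulata	IV	1U	0
umbellulata	II	6U	
umbellulata	III	3U	
umbellulata	IV	2U	
umbellulata	IV	4U	
umbellulata	IV	5U	
umbellulata	IV	7U	
comosa	I	1M	
comosa	I	4M	
comosa	II	2M	
comosa	II	6M	
comosa	III	2M	
comosa	III	5M	
comosa	IV	3M	
comosa	IV	7M	
biuncialis	I	1Ub	
biuncialis	II	3Ub	
biuncialis	II	6Ub	
biuncialis	II	2Mb	
biuncialis	II	3Mb	
biuncialis	II	4Mb	
biuncialis	II	6Mb	
biuncialis	III	2Ub	
biuncialis	III	5Ub	
biuncialis	III	4Ub	
biuncialis	III	7Ub	
biuncialis	III	1Mb	
biuncialis	III	3Mb	
biuncialis	III	5Mb	
biuncialis	IV	7Mb	
geniculata	I	1Ug	
geniculata	I	6Mg	
geniculata	II	3Ug	
geniculata	II	4Ug	
geniculata	II	6Ug	
geniculata	III	2Ug	
geniculata	III	5Ug	
geniculata	III	7Ug	
geniculata	III	2Mg	
geniculata	III	4Mg	
geniculata	III	5Mg	
geniculata	IV	1Mg	
geniculata	IV	3Mg	
geniculata	IV	7Mg	
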