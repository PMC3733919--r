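line_id	species	background	added	removed
CS_1U	umbellulata	CS	1U	
CS_2U	umbellulata	CS	2U	
CS_4U	umbellulata	CS	4U	
CS_5U	umbellulata	CS	5U	
CS_6U	umbellulata	CS	6U	
CS_7U	umbellulata	CS	7U	
CS_2M	comosa	CS	2M	
CS_3M	comosa	CS	3M	
CS_4M	comosa	CS	4M	
CS_5M	comosa	CS	5M	
CS_6M	comosa	CS	6M	
CS_7M	comosa	CS	7M	
CS_6M(6A)	comosa	CS	6M	6A
Mv9kr1_1Ub	biuncialis	Mv9kr1	1Ub	
Mv9kr1_1Ub6Ub	biuncialis	Mv9kr1	1Ub,6Ub	
Mv9kr1_3Ub	biuncialis	Mv9kr1	3Ub	
Mv9kr1_2Mb	biuncialis	Mv9kr1	2Mb	
Mv9kr1_3Mb	biuncialis	Mv9kr1	3Mb	
Mv9kr1_7Mb	biuncialis	Mv9kr1	7Mb	
Mv9kr1_3Mb(4B)	biuncialis	Mv9kr1	3Mb	4B
Mv9kr1_3Mb.4BS	biuncialis	Mv9kr1	3MbL,4BS	
CS_1Ug	geniculata	CS	1Ug	
CS_2Ug	geniculata	CS	2Ug	
CS_3Ug	geniculata	CS	3Ug	
CS_4Ug	geniculata	CS	4Ug	
CS_5Ug	geniculata	CS	5Ug	
CS_6Ug	geniculata	CS	6Ug	
CS_7Ug	geniculata	CS	7Ug	
CS_1Mg	geniculata	CS	1Mg	
CS_2Mg	geniculata	CS	2Mg	
CS_3Mg	geniculata	CS	3Mg	
CS_5Mg	geniculata	CS	5Mg	
CS_6Mg	geniculata	CS	6Mg	
CS_7Mg	geniculata	CS	7Mg	
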