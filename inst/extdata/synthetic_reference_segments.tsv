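kind	index	start	end
exon	3	0	7
intron	3	7	87
exon	4	87	237
intron	4	237	677
exon	5	677	773
intron	5	773	863
exon	6	863	983
intron	6	983	1063
exon	7	1063	1199
intron	7	1199	1284
exon	8	1284	1291
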