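name	motif	cut_offset
EcoRI	GAATTC	1
EcoRII	CCWGG	0
HhaI	GCGC	3
PstI	CTGCAG	5
DraI	TTTAAA	3
HinfI	GANTC	1
HaeIII	GGCC	2
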