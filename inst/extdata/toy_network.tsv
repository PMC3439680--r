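# synthetic toy functional network (12 genes, hand-written for examples)
GENE01	GENE02	1.0
GENE01	GENE03	0.8
GENE02	GENE03	0.9
GENE02	GENE04	0.7
GENE03	GENE04	1.0
GENE04	GENE05	0.2
GENE05	GENE06	1.0
GENE05	GENE07	0.9
GENE06	GENE07	0.8
GENE06	GENE08	0.6
GENE07	GENE08	1.0
GENE08	GENE09	0.3
GENE09	GENE10	0.5
GENE10	GENE11	0.4
GENE11	GENE12	0.6
GENE09	GENE12	0.2
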