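TOY_MODULE_A	synthetic toy module	GENE01	GENE02	GENE03	GENE04
TOY_MODULE_B	synthetic toy module	GENE05	GENE06	GENE07	GENE08
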