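locus	gene	chromosome
GENE1_P10	GENE1	2
GENE2_P20	GENE2	17
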