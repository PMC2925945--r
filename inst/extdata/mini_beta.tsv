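sample_id	GENE1_P10	GENE2_P20
S1	0.10	0.80
S2	0.25	0.65
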