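sample_id	GENE1_P10	GENE2_P20
S1	0.000001	0.000002
S2	0.0000005	0.0000001
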