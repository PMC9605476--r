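subject_id	gene	dna_change	zygosity
CTRL_001	WNT10A	c.682T>A	HET
CTRL_002	LAMA3	c.7298A>C	HET
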