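gene	rs_id	dna_change	protein_change	protein_domain	consequence	af_nfe	ada	cadd	MutationTaster	FATHMM	FATHMM_MKL	FATHMM_XF	LRT	DEOGEN2	EIGEN	EIGEN_PC	SIFT	SIFT4G	PROVEAN	MVP	REVEL	PrimateAI	MetaSVM	MetaLR	db_pathogenic	db_note
LAMA3		c.7298A>C	p.Asn2433Thr		missense			26.0	Dc	D	D	D	D	D	P	P	D	T	D	B	P	T	D	D	FALSE	synthetic annotation row: only the CADD score (26) is reported for this control-only variant
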