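gene	rs_id	dna_change	protein_change	protein_domain	consequence	af_nfe	ada	cadd	MutationTaster	FATHMM	FATHMM_MKL	FATHMM_XF	LRT	DEOGEN2	EIGEN	EIGEN_PC	SIFT	SIFT4G	PROVEAN	MVP	REVEL	PrimateAI	MetaSVM	MetaLR	db_pathogenic	db_note
CHD7		c.5566G>C	p.Glu1856Gln		missense			24.7	Dc	D	D	D	D	T	P	P	D	D	N	B	B	T	D	D	FALSE	
CREBBP		c.1030C>T	p.Pro344Ser		missense			24.7	Dc	D	D	D	D	D	P	P	T	T	D	B	B	D	T	D	FALSE	
CREBBP		c.4678G>A	p.Glu1560Lys	CBP/p300-type HAT domain	missense			29.0	Dc	D	D	D	D	D	P	P	D	D	D	B	P	D	D	D	FALSE	
EVC	rs753014919	c.1694delC	p.Ala565ValfsTer23		frameshift	7.35e-05																			TRUE	ClinVar pathogenic: Ellis-van Creveld syndrome
LEF1		c.285G>C	p.Lys95Asn		missense			23.4	Dc	D	D	D	D	D	B	P	D	D,T	D	B	P	T	D	D	FALSE	
ROR2		c.1895delC	p.Ser632Ter	Protein kinase domain	stop_gain																				FALSE	
TBX22		c.725C>T	p.Pro242Leu	T-box domain	missense			22.9	Dc	D	D	D	D	D			D	D	D	B	P		D	D	FALSE	
TP63		c.1594C>G	p.Pro532Ala		missense			18.8	Dc	D	D	N	D	T	B	P	T	T	N	B	B	T	D	D	FALSE	
AXIN2		c.2023dupC	p.Arg675ProfsTer32		frameshift																				FALSE	
AXIN2		c.2292_2302delGGTTGTCACTT	p.Val765LeufsTer24	DIX domain	frameshift																				FALSE	
EDA	CM960503	c.206G>C	p.Arg69Pro		missense			23.5	P	D	D		N	T			D	T,D	D,N	P	P		D	D	TRUE	HGMD CM960503: ectodermal dysplasia
EDA		c.840C>A	p.Asn280Lys		missense			24.5	Dc	D	D		D	T			D	T,D	N	P	B		D	D	FALSE	
EDA	rs876657641	c.866G>A	p.Arg289His		missense	0		31.0	Dc	D	D	D	D	D			D	T	N	P	P		D	D	TRUE	ClinVar pathogenic/likely pathogenic: hypohidrotic X-linked ectodermal dysplasia; X-linked selective tooth agenesis
EDAR		c.256A>C	p.Ile86Leu	TNFR-Cys repeat	missense			24.6	Dc	D	D	D	D	T	P	P	T	D	N	P	P	D	D	D	FALSE	
IRF6		c.1015A>G	p.Arg339Gly		missense			28.7	Dc	D	D	D	D	D	P	P	D	D	D	P	P	T	D	D	FALSE	
LAMA3	rs771405735	c.916G>T	p.Glu306Ter	Laminin EGF-like domain	stop_gain	0		38.0	Dc		D	N			P	P						T			FALSE	ClinVar uncertain significance: junctional epidermolysis bullosa gravis of Herlitz
LRP6		c.1418G>C	p.Arg473Pro	LDL-receptor class B repeat	missense			25.0	Dc	D	D	D	D	D	P	P	T	D	D	B	P	D	D	D	FALSE	
LRP6		c.1629C>G	p.Asp543Glu	LDL-receptor class B repeat	missense			21.2	Dc	D	D	N	D	T,D	B	B	D	T	D	B	B	T	T	D	FALSE	
LRP6		c.1735A>G	p.Lys579Glu	LDL-receptor class B repeat	missense			24.8	Dc	D	D	D	D	D,T	P	P	D	D	D	P	P	T	D	D	FALSE	
MSX1		c.365dupG	p.Leu123ThrfsTer52		frameshift																				FALSE	
PAX9		c.406C>T	p.Gln136Ter		stop_gain			39.0	Dc		D	N	D		P	P						T			FALSE	described previously in a Finnish family with non-syndromic oligodontia
WNT10A	rs121908119	c.321C>A	p.Cys107Ter		stop_gain	0.0016		35.0	Dc		D	N	D		P	P						T			TRUE	ClinVar pathogenic: selective tooth agenesis; Schopf-Schulz-Passarge; odonto-onycho-dermal dysplasia
WNT10A	rs141074983	c.337C>T	p.Arg113Cys		missense	0.000265		16.2	Dc	T	D	D		D	B	B	D	D	D	B	B	T	T	T	FALSE	
WNT10A	rs143424659	c.668G>A	p.Arg223His		missense	0		22.8	Dc	T	D	N	D	T	B	P	D	D	N	B	B	D	D	D	FALSE	
WNT10A	rs121908120	c.682T>A	p.Phe228Ile		missense	0.0223		28.4	Dc	D	D	D	D	D	P	P	D	D	D	P	P	T	D	D	TRUE	ClinVar pathogenic: selective tooth agenesis; Schopf-Schulz-Passarge; odonto-onycho-dermal dysplasia
WNT10A	rs772154760	c.695G>A	p.Arg232Gln		missense	1.47e-05		31.0	Dc	T	D	D	D	D	P	P	D	D	D	P	B	D	D	D	FALSE	
WNT10A	rs1553623335	c.1034T>C	p.Phe345Ser		missense			33.0	Dc	D	D	D	D	D	P	P	D	D	D	P	P	D	D	D	FALSE	
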