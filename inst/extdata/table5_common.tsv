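gene	rs_id	protein_effect	allele1	allele2	maf_cases	minor_allele_cases	maf_controls	minor_allele_controls	p_trend	odds_ratio	ci_low	ci_high
AXIN2	rs2240308	p.Pro50Ser	C	T	0.48	C	0.46	T	0.317	1.24	0.82	1.90
AXIN2	rs9915936	p.Pro455Pro	A	G	0.17	A	0.12	A	0.19	1.49	0.82	2.71
AXIN2	rs1133683	p.Pro462Pro	C	T	0.41	C	0.38	C	0.589	1.12	0.73	1.72
EDAR	rs260632	p.Ser250Ser	C	T	0.13	C	0.11	C	0.668	1.15	0.61	2.17
EDAR	rs12623957	p.Cys352Cys	C	T	0.16	C	0.17	C	0.712	1.11	0.63	1.96
EVC	rs35870680	p.Ser83Ser	A	G	0.17	G	0.16	G	0.666	1.13	0.64	1.98
EVC	rs6414624	p.Tyr258His	T	C	0.24	T	0.21	T	0.513	1.19	0.72	1.95
EVC	rs4688963	p.Asn323Asn	T	C	0.23	C	0.32	C	0.049	1.62	1.00	2.63
EVC	rs4688962	p.Leu342Leu	G	C	0.29	C	0.37	C	0.118	1.43	0.91	2.25
EVC	rs33929747	p.Leu356Leu	A	G	0.40	G	0.37	G	0.499	1.16	0.75	1.79
EVC	rs2302075	p.Thr449Lys	C	A	0.31	C	0.24	C	0.15	1.43	0.89	2.28
EVC	rs1383180	p.Arg576Gln	G	A	0.41	A	0.45	A	0.448	1.18	0.77	1.80
EVC	rs11737221	p.Gly618Gly	C	T	0.27	T	0.32	T	0.376	1.23	0.77	1.95
IRF6	rs2013162	p.Ser153Ser	G	T	0.40	T	0.30	T	0.0329	1.60	1.03	2.49
LAMA3	rs9962023	p.Ala967Ala	T	C	0.36	T	0.32	T	0.432	1.20	0.77	1.86
LAMA3	rs867449	p.Gly1420Gly	G	C	0.42	G	0.42	G	0.954	1.01	0.66	1.55
LAMA3	rs12965685	p.Pro1510Pro	C	T	0.42	C	0.42	C	0.894	1.03	0.67	1.58
LAMA3	rs1154226	p.Ala2049Ala	C	G	0.33	G	0.31	G	0.711	1.09	0.69	1.71
LAMA3	rs1154232	p.Asn2815Lys	C	A	0.26	A	0.23	A	0.586	1.15	0.70	1.87
LAMA3	rs1131521	p.Leu2911Leu	C	T	0.26	T	0.23	T	0.586	1.15	0.70	1.87
LRP6	rs2302685	p.Val1062Ile	G	A	0.18	G	0.22	G	0.429	1.24	0.73	2.12
MSX1	rs36059701	p.Ala40Gly	C	G	0.14	G	0.14	G	0.872	1.05	0.58	1.92
PAX9	rs12881240	p.His239His	C	T	0.27	C	0.37	C	0.0758	1.54	0.97	2.44
PAX9	rs4904210	p.Ala240Pro	G	C	0.27	G	0.19	G	0.0695	1.59	0.96	2.62
ROR2	rs10820900	p.Thr245Ala	A	G	0.31	A	0.31	A	0.942	1.02	0.65	1.60
ROR2	rs10761129	p.Val819Ile	G	A	0.27	G	0.32	G	0.244	1.32	0.83	2.11
ROR2	rs10992063	p.Tyr696Tyr	C	T	0.48	T	0.44	T	0.493	1.16	0.76	1.77
ROR2	rs2230577	p.Pro718Pro	C	T	0.12	T	0.10	T	0.489	1.26	0.65	2.46
WNT10A	rs121908120	p.Phe228Ile	T	A	0.16	A	0.004	A	9.15e-07	47.86	6.36	360.45
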