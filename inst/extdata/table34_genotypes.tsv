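subject_id	gene	dna_change	zygosity
TA_1	CREBBP	c.1030C>T	HET
TA_2	TBX22	c.725C>T	HEMI
TA_3	ROR2	c.1895delC	HET
TA_4	CHD7	c.5566G>C	HET
TA_5	LEF1	c.285G>C	HET
TA_6	EDA	c.840C>A	HET
TA_7	AXIN2	c.2023dupC	HET
TA_8	MSX1	c.365dupG	HET
TA_9	LRP6	c.1735A>G	HET
TA_10	IRF6	c.1015A>G	HET
TA_11	LRP6	c.1629C>G	HET
TA_12	AXIN2	c.2292_2302delGGTTGTCACTT	HET
TA_13	LAMA3	c.916G>T	HET
TA_14	LRP6	c.1418G>C	HET
TA_15	PAX9	c.406C>T	HET
TA_16	EDA	c.206G>C	HEMI
TA_17	EDA	c.866G>A	HEMI
TA_18	EDA	c.866G>A	HEMI
TA_19	EDAR	c.256A>C	HET
TA_20	WNT10A	c.682T>A	HOM
TA_21	WNT10A	c.682T>A	HET
TA_21	WNT10A	c.1034T>C	HET
TA_22	WNT10A	c.321C>A	HET
TA_22	WNT10A	c.682T>A	HET
TA_23	WNT10A	c.682T>A	HOM
TA_24	WNT10A	c.682T>A	HOM
TA_25	WNT10A	c.682T>A	HOM
TA_26	WNT10A	c.682T>A	HOM
TA_27	WNT10A	c.682T>A	HOM
TA_28	WNT10A	c.337C>T	HET
TA_28	WNT10A	c.682T>A	HET
TA_29	WNT10A	c.682T>A	HET
TA_30	WNT10A	c.321C>A	HET
TA_31	WNT10A	c.682T>A	HOM
TA_32	WNT10A	c.695G>A	HET
TA_33	WNT10A	c.682T>A	HET
TA_33	TP63	c.1594C>G	HET
TA_34	WNT10A	c.682T>A	HET
TA_34	CREBBP	c.4678G>A	HET
TA_35	WNT10A	c.682T>A	HET
TA_36	WNT10A	c.337C>T	HET
TA_36	EVC	c.1694delC	HET
TA_37	WNT10A	c.668G>A	HET
TA_37	WNT10A	c.682T>A	HET
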