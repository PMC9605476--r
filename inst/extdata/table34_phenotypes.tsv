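subject_id	status	sex	family_history	ectodermal_features	missing_teeth	peg_shaped	n_missing_reported
TA_1	case	female	yes	FALSE	14,15,24,34,35,44,45		7
TA_2	case	male	no	FALSE	15,25,31,34,35,41,45		7
TA_3	case	female	yes	FALSE	17,27,35,45,47		5
TA_4	case	male	unknown	TRUE	12,22		2
TA_5	case	female	no	FALSE	12	22	2
TA_6	case	female	yes	FALSE	12,14,15,16,17,22,24,25,26,27,31,32,33,34,35,36,37,41,42,43,44,45,46,47		24
TA_7	case	female	yes	FALSE	12,13,14,15,16,22,23,24,25,26,31,32,35,36,37,41,42,44,45,46,47		21
TA_8	case	female	yes	FALSE	12,14,15,22,24,25,31,34,35,36,37,41,45,46,47		15
TA_9	case	female	no	FALSE	12,14,15,17,22,23,25,27,35,37,44,45,47		13
TA_10	case	female	no	FALSE	12,14,15,22,24,25,35,36,43,45		10
TA_11	case	male	unknown	TRUE	12,13,15,22,23,32,33,34,43,45		10
TA_12	case	male	no	FALSE	12,22,31,32,41,42,47		7
TA_13	case	female	yes	FALSE	15,17,25,27,32,35,42		7
TA_14	case	female	yes	FALSE	12,13,22,23,25,45		6
TA_15	case	male	yes	TRUE	12,14,16,31,32,33		6
TA_16	case	male	yes	FALSE	12,22,31,41,42		5
TA_17	case	male	yes	FALSE	12,13,22,31,41		5
TA_18	case	male	yes	FALSE	16,35,43,46		4
TA_19	case	male	unknown	FALSE	12,22		2
TA_20	case	female	unknown	FALSE	12,13,14,15,16,22,23,24,25,26,31,33,34,35,36,41,43,44,46,47		20
TA_21	case	male	yes	TRUE	12,13,14,15,22,23,24,25,31,32,33,34,35,37,41,42,43,45,47		19
TA_22	case	male	no	FALSE	12,13,15,22,23,24,25,31,32,33,35,41,42,43,44,45		16
TA_23	case	male	yes	FALSE	14,15,17,22,24,25,27,32,34,35,37,41,42,44,45,47		16
TA_24	case	female	yes	FALSE	12,14,15,16,22,24,25,26,34,35,36,44,45,46		14
TA_25	case	female	no	FALSE	12,14,15,16,22,24,25,31,34,37,41,42,44,47		14
TA_26	case	female	yes	FALSE	14,15,17,22,24,25,27,31,35,37,45,47		12
TA_27	case	male	yes	TRUE	12,13,22,23,31,32,33,41,42,43		10
TA_28	case	female	no	TRUE	13,14,15,23,24,34,35,44,45		9
TA_29	case	female	yes	TRUE	12,14,15,22,24,25,34,35,45		9
TA_30	case	male	yes	FALSE	14,15,24,25,34,35,44,45		8
TA_31	case	male	no	FALSE	16,22,31,32,41,42		6
TA_32	case	female	yes	FALSE	12,22,31,41,45		5
TA_33	case	female	no	FALSE	13,15,25,35,45	12	5
TA_34	case	female	yes	FALSE	35,37,45,47	12	4
TA_35	case	female	yes	FALSE	12,14,22		3
TA_36	case	female	yes	FALSE	12,22		2
TA_37	case	male	no	FALSE	12,22		2
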