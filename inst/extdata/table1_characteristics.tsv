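section	item	n	pct
cases	n_total	65	
cases_gender	males	32	49.23
cases_gender	females	33	50.77
family_history	yes	36	55.39
family_history	no	18	27.69
family_history	unknown	11	16.92
agenesis_type	hypodontia	32	49.23
agenesis_type	oligodontia	33	50.77
teeth_missing	total	469	
tooth_type	second_premolar	128	27.29
tooth_type	lateral_incisor	109	23.24
tooth_type	first_premolar	67	14.29
tooth_type	canine	47	10.02
tooth_type	central_incisor	47	10.02
tooth_type	second_molar	45	9.60
tooth_type	first_molar	26	5.54
tooth_group	premolars	195	41.58
tooth_group	incisors	156	33.26
tooth_group	molars	71	15.14
tooth_group	canines	47	10.02
controls	n_total	127	
controls_gender	males	58	45.67
controls_gender	females	69	54.33
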