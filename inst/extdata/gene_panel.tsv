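gene	chromosome	category	pli
AXIN2	17	known_ta	
CHD7	8	odontogenesis	1.00
CREBBP	16	odontogenesis	1.00
EDA	X	known_ta	
EDAR	2	known_ta	
EVC	4	odontogenesis	
IRF6	1	known_ta	
LAMA3	18	known_ta	0.00
LEF1	4	odontogenesis	0.99
LRP6	12	known_ta	1.00
MSX1	4	known_ta	
PAX9	14	known_ta	
ROR2	9	odontogenesis	
TBX22	X	odontogenesis	
TP63	3	odontogenesis	
WNT10A	2	known_ta	
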