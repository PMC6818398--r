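patient_id	age	sex	path_type	differentiation	tnm_stage
P1	62	Male	ADC	L	III
P2	56	Female	ADC	L	I
P3	57	Male	ADC	L	I
P4	43	Female	ADC	H	I
P5	73	Male	SCC	L	III
P6	65	Male	SCLC	-	I
P7	76	Male	SCC	M	II
P8	73	Male	ADC	L	III
P9	64	Male	ADC	L	II
P10	56	Female	ADC	M	I
P11	64	Male	ADC	M	I
P12	31	Male	ADC	L	III
P13	61	Female	ADC	M	I
P14	73	Female	ADC	H	I
P15	41	Male	ADC	L	III
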