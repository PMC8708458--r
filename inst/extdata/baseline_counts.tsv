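dataset	group	n	recent_antibiotics	recent_antibiotics_pct	smoking_never	smoking_ex	smoking_current	ics	ics_pct	allergy	allergy_pct	male	male_pct
training	exacerbation	41	17	41.5	26	15	0	37	90.2	29	70.1	9	22.0
training	no_exacerbation	211	6	2.8	147	50	13	176	70.1	151	71.6	80	38.0
validation	exacerbation	11	3	27.3	10	1	0	10	90.9	9	81.8	5	45.5
validation	no_exacerbation	98	2	2.0	75	13	10	85	86.7	67	68.4	35	35.7
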