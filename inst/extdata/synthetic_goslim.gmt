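protein_glycosylation	synthetic GO-slim style term	pmt1	pmt5	alg3	ost3	yak1
cytoplasmic_translation	synthetic GO-slim style term	rpl12a	rpl31a	rps27b	rpp2b	fob1
nutrient_signaling	synthetic GO-slim style term	tor1	sch9	gpa2	cyr1	rim15	snf1
stress_response	synthetic GO-slim style term	msn2	msn4	gis1	rim15
carbon_metabolism	synthetic GO-slim style term	hxk2	adr1	cat8	sip4	mig1	snf1
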