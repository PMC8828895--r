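bait	method	bio_rep	tech_rep	prey	spectral_count
TP53	BioID	1	1	KDM2B	14
TP53	BioID	1	1	EP300	9
TP53	BioID	1	1	HSPA8	22
TP53	BioID	1	2	KDM2B	11
TP53	BioID	1	2	EP300	7
TP53	BioID	2	1	KDM2B	16
TP53	BioID	2	1	HSPA8	18
TP53	BioID	2	2	KDM2B	12
TP53	BioID	2	2	EP300	10
MYC	BioID	1	1	TRRAP	25
MYC	BioID	1	1	KAT2A	8
MYC	BioID	2	1	TRRAP	19
MYC	BioID	2	1	KAT2A	11
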