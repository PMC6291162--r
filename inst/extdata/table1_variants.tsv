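proband_id	family_id	monozygotic_set_id	gene	transcript	cdna_change	protein_change	inheritance	site
P1	F1		RALA	NM_005402.3	c.73G>A	p.(V25M)	de_novo	SiteA
P2	F2		RALA	NM_005402.3	c.73G>A	p.(V25M)	de_novo	SiteB
P3	F3		RALA	NM_005402.3	c.73G>A	p.(V25M)	de_novo	SiteC
P4	F4	MZ1	RALA	NM_005402.3	c.73G>T	p.(V25L)	de_novo	SiteD
P5	F4	MZ1	RALA	NM_005402.3	c.73G>T	p.(V25L)	de_novo	SiteD
P6	F5		RALA	NM_005402.3	c.383A>G	p.(K128R)	de_novo	SiteE
P7	F6		RALA	NM_005402.3	c.383A>G	p.(K128R)	de_novo	SiteF
P8	F7		RALA	NM_005402.3	c.389A>G	p.(D130G)	de_novo	SiteF
P9	F8		RALA	NM_005402.3	c.469T>G	p.(S157A)	de_novo	SiteF
P10	F9		RALA	NM_005402.3	c.472_474delGCT	p.(A158del)	de_novo	SiteF
P11	F10		RALA	NM_005402.3	c.526C>T	p.(R176X)	unknown	SiteA
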