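gene	residue	phenotype	citation
KRAS	14	Noonan syndrome	PMID:16474404; PMID:17056636
HRAS	117	Costello syndrome	PMID:17054105
HRAS	146	Costello syndrome	PMID:18247425
ARF1	127	Periventricular nodular heterotopia with microcephaly	PMID:28868155
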