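# SYNTHETIC illustrative GTP/GDP-binding region for RALA (206 aa): 24
# residues assembled from the canonical small-GTPase G-box motifs
# (P-loop/G1, switch I, switch II, G4 NKxD, G5 SAK) shifted to RALA
# numbering. It contains all five residue positions recurrently mutated in
# the cohort (25, 128, 130, 157, 158) and has the published region size, but
# it is NOT the published annotation, which is defined from a ligand-bound
# structure and is supplied by the user in real analyses.
21
22
23
24
25
26
27
28
41
43
46
47
68
70
71
77
126
127
128
130
156
157
158
159
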