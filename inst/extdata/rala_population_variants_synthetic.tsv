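residue	consequence	filter
2	missense	PASS
5	missense	PASS
9	missense	PASS
14	missense	PASS
17	missense	PASS
30	missense	PASS
33	missense	PASS
36	missense	PASS
39	missense	PASS
50	missense	PASS
54	missense	PASS
57	missense	PASS
61	missense	PASS
64	missense	PASS
74	missense	PASS
80	missense	PASS
85	missense	PASS
90	missense	PASS
95	missense	PASS
100	missense	PASS
100	missense	PASS
105	missense	PASS
110	missense	PASS
115	missense	PASS
120	missense	PASS
124	missense	PASS
133	missense	PASS
137	missense	PASS
141	missense	PASS
145	missense	PASS
150	missense	PASS
163	missense	PASS
170	missense	PASS
181	missense	PASS
195	missense	PASS
25	missense	LOW_QUALITY
10	synonymous	PASS
176	nonsense	PASS
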