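proband_id	length_birth_le10	weight_birth_le10	height_lastexam_le10	weight_lastexam_le10	autism_spectrum	hypotonia	able_to_walk	facial_dysmorphism	seizures
P1	-	-	+	+	+	-	+	+	+
P2	-	-	-	+	+	+	-	+	-
P3	-	-	+	+	+	+	+	-	-
P4	+	+	+	+	NR	+	-	+	+
P5	+	-	+	+	NR	+	-	+	+
P6	NR	NR	NR	+	NR	+	-	+	+
P7	-	-	-	+	NR	+	-	+	-
P8	NR	-	+	+	NR	+	-	-	+
P9	-	-	-	-	NR	+	+	+	-
P10	-	-	-	-	NR	+	-	+	-
P11	+	+	+	-	NR	+	-	+	+
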