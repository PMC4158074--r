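taxon	clade	atp8-atp6-N	E-cob	cob-S1	I-cox1	D-Y-cox2	R-nad4L-P-cox3	cox3-A	K-nad4	M-L1-rrnL-V
Hoplopleura akanezumi	A	+	+	+	+	+	+	+	+	-
Hoplopleura kitti	A	+	+	+	+	+	+	+	+	+
Pediculus capitis	B	-	-	-	-	-	-	+	+	-
Pediculus humanus	B	-	-	-	-	-	-	+	+	-
Pthirus pubis	B	-	-	+	-	-	-	+	-	-
Polyplax asiatica	B	-	+	-	-	+	-	+	+	+
Polyplax spinulosa	B	-	+	-	-	+	+	-	+	-
Haematopinus suis	B	+	+	-	+	+	-	+	+	-
Haematopinus apri	B	+	+	-	+	+	-	+	+	-
Haematopinus asini	B	+	+	-	+	+	-	+	+	-
Bothriometopus macrocnemis	NA	-	-	-	-	-	-	-	+	-
Campanulotes bidentatus	NA	-	-	-	-	-	-	-	-	-
Ibidoecus bisignatus	NA	-	-	-	-	-	-	-	-	-
Heterodoxus macropus	NA	-	-	-	-	-	-	-	-	-
Lepidopsocid sp.	NA	-	-	-	-	-	-	-	-	-
Haematomyzus elephantis	NA	-	-	-	+	-	-	-	+	-
Hypothetical insect ancestor	NA	-	-	-	-	-	-	-	-	-
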