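taxon	genus	E-cob-S1-S2	C-nad6-W-L2	rrnS	E-cob-I	K-nad4-atp8-atp6-N	nad2-I-cox1-L2	D-Y-cox2-S1-S2-P-cox3-A	E-cob-V	~Q-~nad1-T-G-nad3-W	cob	R-nad3	G-nad4L-V	F-nad6	L1/L2-rrnS-C	L1-rrnL	S1-N-E	T-D-H	W-S2	cob-S1	G-nad3-V-W-S2	T-D-H-R-nad4L	F-nad6-E-M	L1-rrnS	C
Hoplopleura akanezumi	Hoplopleura	+	+	+	-	-	-	-	-	-	-	-	-	-	-	-	-	-	-	-	-	-	-	-	-
Hoplopleura kitti	Hoplopleura	+	+	+	-	-	-	-	-	-	-	-	-	-	-	-	-	-	-	-	-	-	-	-	-
Polyplax asiatica	Polyplax	-	-	-	+	-	-	-	-	-	-	-	-	-	-	-	-	-	-	-	-	-	-	-	-
Polyplax spinulosa	Polyplax	-	-	-	+	-	-	-	-	-	-	-	-	-	-	-	-	-	-	-	-	-	-	-	-
Haematopinus suis	Haematopinus	-	-	-	-	+	+	+	+	+	-	-	-	-	-	-	-	-	-	-	-	-	-	-	-
Haematopinus apri	Haematopinus	-	-	-	-	+	+	+	+	+	-	-	-	-	-	-	-	-	-	-	-	-	-	-	-
Haematopinus asini	Haematopinus	-	-	-	-	+	+	+	+	+	-	-	-	-	-	-	-	-	-	-	-	-	-	-	-
Pediculus capitis	Pediculus	-	-	-	-	-	-	-	-	-	+	+	+	+	+	+	+	+	+	-	-	-	-	-	-
Pediculus humanus	Pediculus	-	-	-	-	-	-	-	-	-	+	+	+	+	+	+	+	+	+	-	-	-	-	-	-
Pthirus pubis	Pthirus	-	-	-	-	-	-	-	-	-	-	-	-	-	-	-	-	-	-	+	+	+	+	+	+
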