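taxon	genus	clade	mini_id	arrangement	coding_len	ncr_len	seq_id
Hoplopleura akanezumi	Hoplopleura	A	atp8-atp6-N	atp8-atp6-N	898	NA	NA
Hoplopleura akanezumi	Hoplopleura	A	E-cob-S1-S2	E-cob-S1-S2	1309	NA	NA
Hoplopleura akanezumi	Hoplopleura	A	I-cox1	I-cox1	1596	NA	NA
Hoplopleura akanezumi	Hoplopleura	A	D-Y1-cox2	D-Y1-cox2	810	NA	NA
Hoplopleura akanezumi	Hoplopleura	A	R-nad4L-P-cox3-A-T	R-nad4L-P-cox3-A-T	1390	NA	NA
Hoplopleura akanezumi	Hoplopleura	A	nad2	nad2	984	NA	NA
Hoplopleura akanezumi	Hoplopleura	A	K-nad4	K-nad4	1322	NA	NA
Hoplopleura akanezumi	Hoplopleura	A	C-nad6-W-L2	C-nad6-W-L2	678	NA	NA
Hoplopleura akanezumi	Hoplopleura	A	rrnS	rrnS	690	972	NA
Hoplopleura akanezumi	Hoplopleura	A	Y2-rrnL-V	Y2-rrnL-V	1263	808	NA
Hoplopleura akanezumi	Hoplopleura	A	chimera	Y2-prrnL-prrnS	433	NA	NA
Hoplopleura kitti	Hoplopleura	A	atp8-atp6-N	atp8-atp6-N	924	NA	NA
Hoplopleura kitti	Hoplopleura	A	E-cob-S1-S2	E-cob-S1-S2	1304	NA	NA
Hoplopleura kitti	Hoplopleura	A	I-cox1	I-cox1	1644	1181	NA
Hoplopleura kitti	Hoplopleura	A	D-Y-cox2-T	D-Y-cox2-T	904	NA	NA
Hoplopleura kitti	Hoplopleura	A	R-nad4L-P-cox3-A	R-nad4L-P-cox3-A	1250	NA	NA
Hoplopleura kitti	Hoplopleura	A	Q-nad1-G-nad3	~Q-~nad1-G-nad3	1447	NA	NA
Hoplopleura kitti	Hoplopleura	A	nad2	nad2	990	NA	NA
Hoplopleura kitti	Hoplopleura	A	K-nad4	K-nad4	1317	NA	NA
Hoplopleura kitti	Hoplopleura	A	C-nad6-W-L2	C-nad6-W-L2	685	NA	NA
Hoplopleura kitti	Hoplopleura	A	rrnS	rrnS	695	1249	NA
Hoplopleura kitti	Hoplopleura	A	M-L1-rrnL-V	M-L1-rrnL-V	1299	1107	NA
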