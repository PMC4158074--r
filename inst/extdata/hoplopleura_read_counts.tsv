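taxon	mini_id	coding_len	n_reads
Hoplopleura akanezumi	atp8-atp6-N	898	31926
Hoplopleura akanezumi	E-cob-S1-S2	1309	2539
Hoplopleura akanezumi	I-cox1	1596	6545
Hoplopleura akanezumi	D-Y1-cox2	810	55030
Hoplopleura akanezumi	R-nad4L-P-cox3-A-T	1390	1706
Hoplopleura akanezumi	nad2	984	22613
Hoplopleura akanezumi	K-nad4	1322	2059
Hoplopleura akanezumi	C-nad6-W-L2	678	33296
Hoplopleura akanezumi	rrnS	690	166399
Hoplopleura akanezumi	Y2-rrnL-V	1263	50213
Hoplopleura akanezumi	chimera	433	237554
Hoplopleura kitti	atp8-atp6-N	924	99377
Hoplopleura kitti	E-cob-S1-S2	1304	52216
Hoplopleura kitti	I-cox1	1644	35537
Hoplopleura kitti	D-Y-cox2-T	904	42531
Hoplopleura kitti	R-nad4L-P-cox3-A	1250	59511
Hoplopleura kitti	Q-nad1-G-nad3	1447	51409
Hoplopleura kitti	nad2	990	50604
Hoplopleura kitti	K-nad4	1317	41629
Hoplopleura kitti	C-nad6-W-L2	685	60815
Hoplopleura kitti	rrnS	695	88891
Hoplopleura kitti	M-L1-rrnL-V	1299	60799
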