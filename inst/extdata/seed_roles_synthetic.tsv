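id	bacteriocin	role	subgroup	leader_length
prec_amylocyclicin	amylocyclicin	precursor	i	48
prec_amylocyclicin_CMW1	amylocyclicin_CMW1	precursor	i	44
prec_enterocin_NKR-5-3B	enterocin_NKR-5-3B	precursor	i	23
prec_uberolysin	uberolysin	precursor	i	6
prec_enterocin_AS-48	enterocin_AS-48	precursor	i	35
prec_pumilarin	pumilarin	precursor	i	35
prec_BacA	BacA	precursor	i	33
prec_acidocin_B	acidocin_B	precursor	ii	33
prec_gassericin_A	gassericin_A	precursor	ii	33
prec_butyrovibriocin_AR10	butyrovibriocin_AR10	precursor	ii	22
prec_plantaricyclin_A	plantaricyclin_A	precursor	ii	18
prec_plantacyclin_B21AG	plantacyclin_B21AG	precursor	ii	12
prec_paracyclicin	paracyclicin	precursor	ii	6
prec_thermocin_485	thermocin_485	precursor	i	3
prec_circularin_A	circularin_A	precursor	i	3
prec_carnocyclin_A	carnocyclin_A	precursor	i	4
prec_aureocyclicin_4185	aureocyclicin_4185	precursor	i	12
prec_leucocyclicin_Q	leucocyclicin_Q	precursor	i	2
prec_garvicin_ML	garvicin_ML	precursor	i	3
tra_amylocyclicin	amylocyclicin	transporter	i	NA
tra_amylocyclicin_CMW1	amylocyclicin_CMW1	transporter	i	NA
tra_enterocin_NKR-5-3B	enterocin_NKR-5-3B	transporter	i	NA
tra_uberolysin	uberolysin	transporter	i	NA
tra_enterocin_AS-48	enterocin_AS-48	transporter	i	NA
tra_pumilarin	pumilarin	transporter	i	NA
tra_BacA	BacA	transporter	i	NA
tra_acidocin_B	acidocin_B	transporter	ii	NA
tra_gassericin_A	gassericin_A	transporter	ii	NA
tra_butyrovibriocin_AR10	butyrovibriocin_AR10	transporter	ii	NA
tra_plantaricyclin_A	plantaricyclin_A	transporter	ii	NA
tra_plantacyclin_B21AG	plantacyclin_B21AG	transporter	ii	NA
tra_paracyclicin	paracyclicin	transporter	ii	NA
tra_thermocin_485	thermocin_485	transporter	i	NA
tra_circularin_A	circularin_A	transporter	i	NA
tra_carnocyclin_A	carnocyclin_A	transporter	i	NA
tra_aureocyclicin_4185	aureocyclicin_4185	transporter	i	NA
tra_leucocyclicin_Q	leucocyclicin_Q	transporter	i	NA
tra_garvicin_ML	garvicin_ML	transporter	i	NA
spo_amylocyclicin	amylocyclicin	spoIIM	i	NA
spo_amylocyclicin_CMW1	amylocyclicin_CMW1	spoIIM	i	NA
spo_enterocin_NKR-5-3B	enterocin_NKR-5-3B	spoIIM	i	NA
spo_uberolysin	uberolysin	spoIIM	i	NA
spo_enterocin_AS-48	enterocin_AS-48	spoIIM	i	NA
spo_pumilarin	pumilarin	spoIIM	i	NA
spo_BacA	BacA	spoIIM	i	NA
spo_acidocin_B	acidocin_B	spoIIM	ii	NA
spo_gassericin_A	gassericin_A	spoIIM	ii	NA
spo_butyrovibriocin_AR10	butyrovibriocin_AR10	spoIIM	ii	NA
spo_plantaricyclin_A	plantaricyclin_A	spoIIM	ii	NA
spo_plantacyclin_B21AG	plantacyclin_B21AG	spoIIM	ii	NA
spo_paracyclicin	paracyclicin	spoIIM	ii	NA
spo_thermocin_485	thermocin_485	spoIIM	i	NA
spo_circularin_A	circularin_A	spoIIM	i	NA
spo_carnocyclin_A	carnocyclin_A	spoIIM	i	NA
spo_aureocyclicin_4185	aureocyclicin_4185	spoIIM	i	NA
spo_leucocyclicin_Q	leucocyclicin_Q	spoIIM	i	NA
spo_garvicin_ML	garvicin_ML	spoIIM	i	NA
yip1_a	generic	yip1	unknown	NA
yip1_b	generic	yip1	unknown	NA
peptidase_M48	generic	peptidase	unknown	NA
peptidase_M50	generic	peptidase	unknown	NA
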