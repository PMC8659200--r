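bacteriocin	seed_id	leader_length
amylocyclicin	prec_amylocyclicin	48
amylocyclicin_CMW1	prec_amylocyclicin_CMW1	44
enterocin_NKR-5-3B	prec_enterocin_NKR-5-3B	23
uberolysin	prec_uberolysin	6
enterocin_AS-48	prec_enterocin_AS-48	35
pumilarin	prec_pumilarin	35
BacA	prec_BacA	33
acidocin_B	prec_acidocin_B	33
gassericin_A	prec_gassericin_A	33
butyrovibriocin_AR10	prec_butyrovibriocin_AR10	22
plantaricyclin_A	prec_plantaricyclin_A	18
plantacyclin_B21AG	prec_plantacyclin_B21AG	12
paracyclicin	prec_paracyclicin	6
thermocin_485	prec_thermocin_485	3
circularin_A	prec_circularin_A	3
carnocyclin_A	prec_carnocyclin_A	4
aureocyclicin_4185	prec_aureocyclicin_4185	12
leucocyclicin_Q	prec_leucocyclicin_Q	2
garvicin_ML	prec_garvicin_ML	3
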