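stimulus	family
geon01	fam1
geon02	fam1
geon03	fam1
geon04	fam2
geon05	fam2
geon06	fam2
geon07	fam3
geon08	fam3
geon09	fam3
geon10	fam4
geon11	fam4
geon12	fam4
geon13	fam5
geon14	fam5
geon15	fam5
geon16	fam6
geon17	fam6
geon18	fam6
geon19	fam7
geon20	fam7
geon21	fam7
geon22	fam8
geon23	fam8
geon24	fam8
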