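label	transcription
ent01	miri
ent02	kari
ent03	kazeloba
ent04	nuvu
ent05	vurita
ent06	nunutata
ent07	nunuka
ent08	tadoba
ent09	pevuvupe
ent10	midomivu
ent11	ripe
ent12	sodo
ent13	riso
ent14	vurilo
ent15	pesoka
ent16	kape
ent17	pebalo
ent18	soperido
ent19	sorize
ent20	miso
ent21	tari
ent22	mirido
ent23	dodoba
ent24	nupe
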