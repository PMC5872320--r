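place	region	plant_id	locality	cr_percent
El Granel	La Palma	LP1	EG	48.28
El Palmar-Teno	Tenerife	TF8	EP	25
Granadilla	Tenerife	TF7	GR	25
Igueste Caletillas	Tenerife	TF4	IC	50
Mesa Mota	Tenerife	TF1	MM	62.5
Mesa Mota	Tenerife	TF2	MM	62.5
San Andres	Tenerife	TF5	SA	62.5
San Bartolo	La Palma	LP2	SB	92.11
Taborno	Tenerife	TF3	TA	25
Tigalate	La Palma	LP4	TIG	55
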