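plant_id	locality	species	cf_percent
LP1	EG	Alternaria alternata	24.14
LP1	EG	Alternaria sp. 5	13.79
LP1	EG	Aspergillus flavus	3.45
LP1	EG	Aspergillus flavus	6.9
LP1	EG	Diaporthe novem	3.45
LP1	EG	Fungus sp. 1	3.45
LP1	EG	Neofusicoccum parvum	3.45
LP1	EG	Nigrospora oryzae	3.45
LP1	EG	Penicillium viridicatum	3.45
LP1	EG	Phoma sp. 3	3.45
LP1	EG	Pleosporales sp. 2	6.9
LP1	EG	Preussia sp. 3	3.45
LP2	SB	Alternaria alternata	10.53
LP2	SB	Alternaria sp. 5	2.63
LP2	SB	Camarosporium bradgi	2.63
LP2	SB	Coniothyrium sp. 1	2.63
LP2	SB	Diaporthe phaseolorum	7.89
LP2	SB	Diaporthe sp. 1	5.26
LP2	SB	Dothideomycetes sp. 1	2.63
LP2	SB	Fungus sp. 1	2.63
LP2	SB	Neofusicoccum parvum	13.16
LP2	SB	Neofusicoccum sp. 3	34.21
LP2	SB	Neoplatysporoides aloicola	5.26
LP2	SB	Nigrospora sp. 2	2.63
LP2	SB	Pleosporales sp. 3	2.63
LP2	SB	Preussia sp. 3	2.63
LP2	SB	Tremateia sp. 1	2.63
LP4	TIG	Alternaria alternata	15
LP4	TIG	Curvularia lunata	5
LP4	TIG	Neofusicoccum sp. 1	5
LP4	TIG	Paraphoma cf. chrysantemicola	5
LP4	TIG	Preussia sp. 1	25
TF1	MM	Alternaria alternata	25
TF1	MM	Thielavia sp. 1	8.33
TF2	MM	Alternaria alternata	50
TF2	MM	Biscogniauxia mediterrranea	12.5
TF2	MM	Neofusicoccum australe	12.5
TF2	MM	Phoma sp. 1	12.5
TF3	TA	Neofusicoccum australe	25
TF4	IC	Alternaria alternata	37.5
TF4	IC	Aureobasidium pullulans	12.5
TF5	SA	Alternaria alternata	12.5
TF5	SA	Alternaria sp. 6	12.5
TF5	SA	Macrophomina phaseolina	25
TF5	SA	Stachybotrys longispora	12.5
TF7	GR	Alternaria alternata	25
TF7	GR	Neofusicoccum australe	25
TF7	GR	Stemphylium solani	25
TF8	EP	Camarosporium sp. 1	12.5
TF8	EP	Phoma sp. 1	12.5
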