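species	cf_percent
Alternaria alternata	18.71
Alternaria sp. 5	3.23
Alternaria sp. 6	0.65
Aspergillus flavus	1.94
Aureobasidium pullulans	0.65
Biscogniauxia mediterrranea	0.65
Camarosporium bradgi	0.65
Camarosporium sp. 1	0.65
Coniothyrium sp. 1	0.65
Curvularia lunata	0.65
Diaporthe novem	0.65
Diaporthe phaseolorum	1.94
Diaporthe sp. 1	1.29
Dothideomycetes sp. 1	0.65
Fungus sp. 1	1.29
Macrophomina phaseolina	1.29
Neofusicoccum australe	2.58
Neofusicoccum parvum	3.87
Neofusicoccum sp. 1	0.65
Neofusicoccum sp. 3	8.39
Neoplatysporoides aloicola	1.29
Nigrospora oryzae	0.65
Nigrospora sp. 2	0.65
Paraphoma chrysantemicola	0.65
Penicillium viridicatum	0.65
Phoma sp. 1	1.29
Phoma sp. 3	0.65
Pleosporales sp. 2	1.29
Pleosporales sp. 3	0.65
Preussia sp. 1	3.23
Preussia sp. 3	1.29
Stachybotrys longispora	0.65
Stemphylium solani	0.65
Tremateia sp. 1	1.94
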