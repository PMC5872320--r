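species	plant_id	cf_plant	cf_pda	cf_lca	cf_v8	cf_age_le1	cf_age_gt1
Alternaria alternata	TF2	50	50	37.5	62.5	41.67	58.33
Alternaria sp. 4	TF2	4.17		12.5			8.33
Biscogniauxia mediterrranea	TF2	4.17	12.5			8.33	
Neofusicoccum australe	TF2	16.67	12.5	12.5	12.5	16.67	8.33
Pestalotiopsis sp.	TF2	4.17		12.5		8.33	
Phoma sp. 1	TF2	4.17	12.5				8.33
Neofusicoccum australe	TF3	8.33	25			16.67	
Neofusicoccum parvum	TF3	8.33		12.5	12.5	16.67	
Pestalotiopsis sp.	TF3	4.17		12.5		8.33	
Alternaria alternata	TF4	12.5	37.5			16.67	8.33
Aureobasidium pullulans	TF4	4.17	12.5			8.33	
Nectria mauritiicola	TF4	8.33		25			16.67
Alternaria alternata	TF5	37.5	12.5	50	50	8.33	66.67
Alternaria sp. 6	TF5	4.17	12.5			8.33	
Aplosporella prunicola	TF5	4.17		12.5		8.33	
Aureobasidium pullulans	TF5	4.17		12.5			8.33
Macrophomina phaseolina	TF5	8.33	25				16.67
Neofusicoccum australe	TF5	4.17		12.5		8.33	
Stachybotrys longispora	TF5	4.17	12.5			8.33	
Stemphylium solani	TF5	8.33		12.5	12.5	16.67	
Alternaria alternata	TF7	8.33	8.33	12.5	12.5		16.67
Aureobasidium pullulans	TF7	12.5		12.5		8.33	
Chaetomium sp. 1	TF7	16.67			25		16.67
Cladosporium sp. 1	TF7	12.5			25	16.67	
Neofusicoccum australe	TF7	8.33			12.5		8.33
Phoma sp. 1	TF7	16.67		50		33.33	
Preussia australis	TF7	8.33	12.5				8.33
Stemphylium solani	TF7	4.17	12.5			8.33	
Biscogniauxia mediterrranea	TF8	8.33			12.5		8.33
Camarosporium sp. 1	TF8	8.33	12.5				8.33
Phoma sp. 1	TF8	16.67	12.5			8.33	
Preussia sp. 2	TF8	16.67			37.5		25
Preussia sp. 3	TF8	12.5		12.5			8.33
Preussia sp. 5	TF8	12.5		25			16.67
Stemphylium solani	TF8	4.17		12.5			8.33
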