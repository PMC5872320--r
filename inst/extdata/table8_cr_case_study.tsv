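plant_id	cr_plant	cr_pda	cr_lca	cr_v8	cr_age_le1	cr_age_gt1
TF3	16.67	25	12.5	12.5	33.33	0
TF4	16.67	37.5	12.5	0	8.33	25
TF5	58.33	62.5	75	37.5	58.33	41.67
TF7	45.83	25	50	62.5	50	41.67
TF8	37.5	25	37.5	50	8.33	66.67
AVG	35.12	33.93	33.93	37.5	30.95	36.9
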