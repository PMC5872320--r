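sample_id	taxa	strains	simpson_1d	brillouin	margalef	fisher_alpha
LP1/EG	11	15	0.89	1.65	3.69	18.6
LP2/SB	15	27	0.87	1.85	4.25	13.9
LP4/TIG	5	5	0.8	0.96	2.49	0
TF1/MM	5	10	0.6	0.85	1.74	3.98
TF3/TA	1	2	0	0	0	0.8
TF4/IC	2	3	0.44	0.37	0.91	2.62
TF5/SA	4	5	0.72	0.82	1.86	9.28
TF7/GR	3	3	0.67	0.6	1.82	0
TF8/EP	2	2	0.5	0.35	1.44	0
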