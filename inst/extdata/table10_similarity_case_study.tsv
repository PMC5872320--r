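sample_a	sample_b	similarity
PDA	LCA	0.42
PDA	V8	0.48
PDA	le_1yr	0.64
PDA	gt_1yr	0.71
LCA	V8	0.52
LCA	le_1yr	0.67
LCA	gt_1yr	0.67
V8	le_1yr	0.67
V8	gt_1yr	0.59
le_1yr	gt_1yr	0.43
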