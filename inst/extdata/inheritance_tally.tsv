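variant_class	de_novo	inherited	unknown
LGD	114	1	24
MIS_noCADD	4	0	4
MIS20	42	1	30
MIS30	4	0	1
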