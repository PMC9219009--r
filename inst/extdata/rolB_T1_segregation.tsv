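line	resistant	sensitive	expected_ratio
Nontransformed	0	175	3:1
EV2	93	41	3:1
cRolB1	163	26	6:1
cRolB2	121	45	3:1
cRolB3	65	46	2:1
cRolB7	66	34	2:1
cRolB8	60	36	2:1
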