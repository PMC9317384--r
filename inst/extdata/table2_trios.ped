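F1	P1	F1_fa	F1_mo	0	2
F1	F1_fa	0	0	1	1
F1	F1_mo	0	0	2	1
F2	P2	F2_fa	F2_mo	0	2
F2	F2_fa	0	0	1	1
F2	F2_mo	0	0	2	1
F3	P3	F3_fa	F3_mo	0	2
F3	F3_fa	0	0	1	1
F3	F3_mo	0	0	2	1
F4	P4	F4_fa	F4_mo	0	2
F4	P5	F4_fa	F4_mo	0	2
F4	F4_fa	0	0	1	1
F4	F4_mo	0	0	2	1
F5	P7	P8	F5_mo	0	2
F5	P8	0	0	1	2
F5	F5_mo	0	0	2	1
F6	P6	F6_fa	F6_mo	0	2
F6	F6_fa	0	0	1	1
F6	F6_mo	0	0	2	1
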