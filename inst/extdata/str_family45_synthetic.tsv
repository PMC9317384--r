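individual	marker	allele1	allele2
F4_fa	D11S4197	150	154
F4_fa	D11S4147	204	208
F4_fa	D11S1298	178	182
F4_fa	D11S937	132	136
F4_fa	D11S4162	246	250
F4_fa	D11S1392	188	192
F4_fa	D11S4174	160	164
F4_fa	D11S4207	212	216
F4_fa	D11S1358	196	200
F4_mo	D11S4197	158	162
F4_mo	D11S4147	212	216
F4_mo	D11S1298	186	190
F4_mo	D11S937	140	144
F4_mo	D11S4162	254	258
F4_mo	D11S1392	196	200
F4_mo	D11S4174	168	172
F4_mo	D11S4207	220	224
F4_mo	D11S1358	204	208
P4	D11S4197	150	158
P4	D11S4147	204	212
P4	D11S1298	178	186
P4	D11S937	132	140
P4	D11S4162	246	254
P4	D11S1392	188	196
P4	D11S4174	160	168
P4	D11S4207	212	220
P4	D11S1358	196	204
P5	D11S4197	150	158
P5	D11S4147	204	212
P5	D11S1298	178	186
P5	D11S937	132	140
P5	D11S4162	246	254
P5	D11S1392	188	196
P5	D11S4174	160	168
P5	D11S4207	212	220
P5	D11S1358	196	204
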