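host	event	region	segments	infected	isolates
Aglaia elaeagnoidea	1	midrib	75	15	17
Aglaia elaeagnoidea	1	lamina	75	8	8
Aglaia elaeagnoidea	2	midrib	75	24	24
Aglaia elaeagnoidea	2	lamina	75	17	17
Flacourtia inermis	1	midrib	75	24	31
Flacourtia inermis	1	lamina	75	12	13
Flacourtia inermis	2	midrib	75	34	39
Flacourtia inermis	2	lamina	75	22	22
Premna serratifolia	1	midrib	75	61	69
Premna serratifolia	1	lamina	75	42	44
Premna serratifolia	2	midrib	75	51	61
Premna serratifolia	2	lamina	75	45	47
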