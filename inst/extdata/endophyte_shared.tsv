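host1	host2	s1	s2	shared
Aglaia elaeagnoidea	Flacourtia inermis	21	20	6
Aglaia elaeagnoidea	Premna serratifolia	21	23	8
Flacourtia inermis	Premna serratifolia	20	23	6
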