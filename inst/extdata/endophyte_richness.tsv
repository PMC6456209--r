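host	isolates	morphotypes	species
Aglaia elaeagnoidea	66	29	21
Flacourtia inermis	105	32	20
Premna serratifolia	221	37	23
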