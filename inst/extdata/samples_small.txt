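id population
ind1 A
ind2 A
ind3 A
ind4 B
ind5 B
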