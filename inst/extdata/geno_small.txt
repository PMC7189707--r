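id population snp1 snp2 snp3 snp4
ind1 A 0 1 2 2
ind2 A 1 1 0 2
ind3 A 2 0 1 1
ind4 B 0 2 2 0
ind5 B 1 2 1 0
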