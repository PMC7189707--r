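FID IID PAT MAT SEX PHENOTYPE snp1_A snp2_C snp3_G snp4_T
fam1 ind1 0 0 1 -9 0 1 2 2
fam1 ind2 0 0 1 -9 1 1 0 2
fam1 ind3 0 0 2 -9 2 0 1 1
fam2 ind4 0 0 1 -9 0 2 2 0
fam2 ind5 0 0 2 -9 1 2 1 0
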