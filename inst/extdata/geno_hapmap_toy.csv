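marker,chrom,pos,alleles,ind1,ind2,ind3
snp1,1,1000,A/G,AA,AG,GG
snp2,1,2500,C/T,CT,CT,TT
snp3,2,500,A/C,CC,CC,AA
snp4,2,1800,G/T,GG,NN,GT
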