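marker,chrom,pos,ind1,ind2,ind3
snp1,1,1000,1,0,-1
snp2,1,2500,0,0,1
snp3,2,500,-1,-1,1
snp4,2,1800,1,,0
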