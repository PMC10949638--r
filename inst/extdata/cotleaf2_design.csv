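environment,year,n_genotypes,plants_per_genotype,images_per_plant
FD,Y3,27,10,1
GH,Y3,27,10,1
FD,Y4,27,10,1
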