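ghs,n_images,n_genotypes
1,152,3
2,40,1
3,160,3
3/4,180,4
4,238,5
4/4+,200,4
4+,240,4
5,40,1
5+,0,0
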