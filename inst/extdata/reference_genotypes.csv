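genotype,ghs
pink,1
red,1
azure,1
charcoal,2
scarlet,3
indigo,3
purple,3
white,3/4
opal,3/4
ebony,3/4
bronze,3/4
amber,4
emerald,4
copper,4
yellow,4
orange,4
teal,4/4+
beige,4/4+
green,4/4+
violet,4/4+
crimson,4+
cyan,4+
blue,4+
gray,4+
turquoise,5
brown,5+
black,5+
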