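genus	n_human_species
Escherichia	4
Pseudomonas	3
Acinetobacter	2
Cutibacterium	3
Burkholderia	2
Ralstonia	1
Sphingomonas	0
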