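# Illustrative frequent-NGS-contaminant genus list (Salter-style).
# One genus per line; lines starting with '#' are comments.
Ralstonia
Burkholderia
Bradyrhizobium
Methylobacterium
Sphingomonas
Cutibacterium
Escherichia
Pseudomonas
Acinetobacter
Herbaspirillum
Phyllobacterium
Stenotrophomonas
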