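cell_type	gene
Tcell	CD3D
Tcell	CD3E
Bcell	MS4A1
Bcell	CD79A
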