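100.00	100	40	R	1	root
60.00	60	10	P	201	  Phylum_P
50.00	50	50	G	301	    Genus_G
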