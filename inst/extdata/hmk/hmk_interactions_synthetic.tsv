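protein_a	protein_b	site_a	site_b	rate_tag	switch_tag
Hec1	MT	mt	hec1		
Ska3	MT	mt	ska3		
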