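context	base	prob
	A	0.25
	C	0.25
	G	0.25
	T	0.25
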