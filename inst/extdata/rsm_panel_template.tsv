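sample_id	source_type	cp	ee	starch	ndf	adf	cf	ash	ge	de	me	ne
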