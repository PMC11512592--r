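pos	alt	source
664	T	curated
819	A	curated
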