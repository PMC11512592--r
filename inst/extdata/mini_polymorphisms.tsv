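pos	alt	frequency
745	G	0.12
819	A	0.03
996	T	0.4
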