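pos	ref	alt	phred
342	T	G	0.57
664	A	T	11.81
745	A	G	4.71
757	T	C	1.84
819	G	A	7.52
941	G	T	33.5
972	T	C	17.5
996	A	T	13.32
1195	G	A	17.32
1248	T	A	32.28
1311	G	A	30.44
1559	A	C	6.85
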