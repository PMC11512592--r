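name	kind	start	end	strand	frame_start
DLOOP	dloop	1851	150	.	.
LC1	low_complexity	60	80	.	.
LC2	low_complexity	1201	1215	.	.
PG1	protein	301	900	heavy	301
TR1	tRNA	920	990	heavy	.
PG2	protein	1001	1600	light	1600
RR1	rRNA	1650	1800	heavy	.
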