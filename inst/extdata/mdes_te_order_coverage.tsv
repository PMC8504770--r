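code	order_label	consensus_count_r1	coverage_pct_r1	coverage_bp_r1	consensus_count_flc	coverage_pct_flc	coverage_bp_flc
RLX	LTR	45	1.26	1932824	38	1.17	1789590
RIX	LINE	28	0.37	568834	28	0.39	590859
RSX	SINE	3	0.04	65866	3	0.03	52834
RPX	Penelope	5	0.05	72120	2	0.02	26689
RXX	TRIM	3	0.01	13707	2	0.01	12372
DTX	TIR	90	1.13	1727136	79	1.03	1575291
MITE	MITE	83	0.89	1360651	84	0.87	1338036
DHX	Helitron	7	0.08	120684	7	0.08	121020
DMX	Maverick	11	0.15	228938	10	0.15	228968
DXX	Unknown_transposons	1	0.01	19151	1	0.01	19148
PHG	PHG	44	0.98	1507976	43	0.981	1502303
noCat	noCat	843	11.85	18148362	738	11.6	17775484
SSR	SSR	5	0.02	31970	3	0.02	32341
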