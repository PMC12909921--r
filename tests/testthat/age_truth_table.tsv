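M_bellicosus	O_sp2	T_geminatus	R_grassei	C_secundus	Z_nevadensis	age_group
1	0	0	0	0	0	M_bellicosus
0	1	0	0	0	0	O_sp2
1	1	0	0	0	0	Macrotermitinae
0	0	1	0	0	0	Termitidae
1	0	1	0	0	0	unknown
0	1	1	0	0	0	Termitidae
1	1	1	0	0	0	Termitidae
0	0	0	1	0	0	Geoisoptera
1	0	0	1	0	0	unknown
0	1	0	1	0	0	unknown
1	1	0	1	0	0	unknown
0	0	1	1	0	0	Geoisoptera
1	0	1	1	0	0	unknown
0	1	1	1	0	0	Geoisoptera
1	1	1	1	0	0	Geoisoptera
0	0	0	0	1	0	ancient
1	0	0	0	1	0	unknown
0	1	0	0	1	0	unknown
1	1	0	0	1	0	unknown
0	0	1	0	1	0	unknown
1	0	1	0	1	0	unknown
0	1	1	0	1	0	unknown
1	1	1	0	1	0	unknown
0	0	0	1	1	0	ancient
1	0	0	1	1	0	unknown
0	1	0	1	1	0	unknown
1	1	0	1	1	0	unknown
0	0	1	1	1	0	ancient
1	0	1	1	1	0	unknown
0	1	1	1	1	0	ancient
1	1	1	1	1	0	ancient
0	0	0	0	0	1	ancient
1	0	0	0	0	1	unknown
0	1	0	0	0	1	unknown
1	1	0	0	0	1	unknown
0	0	1	0	0	1	unknown
1	0	1	0	0	1	unknown
0	1	1	0	0	1	unknown
1	1	1	0	0	1	unknown
0	0	0	1	0	1	ancient
1	0	0	1	0	1	unknown
0	1	0	1	0	1	unknown
1	1	0	1	0	1	unknown
0	0	1	1	0	1	ancient
1	0	1	1	0	1	unknown
0	1	1	1	0	1	ancient
1	1	1	1	0	1	ancient
0	0	0	0	1	1	ancient
1	0	0	0	1	1	unknown
0	1	0	0	1	1	unknown
1	1	0	0	1	1	unknown
0	0	1	0	1	1	unknown
1	0	1	0	1	1	unknown
0	1	1	0	1	1	unknown
1	1	1	0	1	1	unknown
0	0	0	1	1	1	ancient
1	0	0	1	1	1	unknown
0	1	0	1	1	1	unknown
1	1	0	1	1	1	unknown
0	0	1	1	1	1	ancient
1	0	1	1	1	1	unknown
0	1	1	1	1	1	ancient
1	1	1	1	1	1	ancient
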