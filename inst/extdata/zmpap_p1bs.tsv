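gene	p1bs_count	p1bs_locations	localization
ZmPap26	1	-2352	S
ZmPap30a	1	-256	S
ZmPap30b	0		S
ZmPap10	2	-232,-2463	S
ZmPap23	1	-199	M
ZmPap13	1	-412	S
ZmPap21a	0		S
ZmPap21b	0		O
ZmPap21c	4	-326,-1676,-1773,-1819	S
ZmPap21d	2	-1462,-2357	S
ZmPap18	0		S
ZmPap2a	2	-138,-2268	S
ZmPap2b	1	-618	M
ZmPap2c	2	-2038,-2140	O
ZmPap2d	2	-498,-791	C
ZmPap2e	1	-824	C
ZmPap2f	0		O
ZmPap1a	2	-391,-451	M
ZmPap1b	1	-2147	M
ZmPap1c	1	-191	M
ZmPap24a	0		S
ZmPap24b	0		S
ZmPap7a	0		S
ZmPap7b	0		O
ZmPap7c	0		S
ZmPap7d	4	-436,-666,-708,-1811	S
ZmPap7e	1	-446	O
ZmPap7f	0		O
ZmPap7g	1	-1368	M
ZmPap14	0		M
ZmPap16	1	-266	M
ZmPap28a	0		S
ZmPap28b	0		S
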