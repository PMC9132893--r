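symbol	family	length
TRPA1	TRPA	1119
TRPC1	TRPC	793
TRPC2	TRPC	1172
TRPC3	TRPC	848
TRPC4	TRPC	977
TRPC5	TRPC	973
TRPC6	TRPC	931
TRPC7	TRPC	862
TRPM1	TRPM	1603
TRPM2	TRPM	1503
TRPM3	TRPM	1707
TRPM4	TRPM	1214
TRPM5	TRPM	1165
TRPM6	TRPM	2022
TRPM7	TRPM	1865
TRPM8	TRPM	1104
TRPV1	TRPV	839
TRPV2	TRPV	764
TRPV3	TRPV	790
TRPV4	TRPV	871
TRPV5	TRPV	729
TRPV6	TRPV	725
MCOLN1	TRPML	580
MCOLN2	TRPML	566
MCOLN3	TRPML	553
PKD2	TRPP	968
PKD2L1	TRPP	805
PKD2L2	TRPP	624
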