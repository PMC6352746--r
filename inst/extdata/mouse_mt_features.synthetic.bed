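mt	0	68	tRNA-Phe	0	+
mt	68	1024	s-rRNA	0	+
mt	1024	1093	tRNA-Val	0	+
mt	1093	2675	l-rRNA	0	+
mt	2675	2750	tRNA-Leu1	0	+
mt	2750	3707	ND1	0	+
mt	5159	5191	OriL	0	+
mt	5328	6872	COX1	0	+
mt	9459	10125	COX3	0	+
mt	11544	11612	tRNA-His	0	+
mt	15288	15355	tRNA-Thr	0	-
mt	15422	16299	D-loop	0	+
mt	16030	16060	CSB1	0	+
mt	16105	16130	CSB2	0	+
mt	16180	16210	CSB3	0	+
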