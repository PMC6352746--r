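position	mt_allele	numt_allele	source_id
1290	A	G	synthetic_demo
2481	T	C	synthetic_demo
3905	G	A	synthetic_demo
5212	C	T	synthetic_demo
6740	A	C	synthetic_demo
8122	T	G	synthetic_demo
9618	G	T	synthetic_demo
11002	C	A	synthetic_demo
12575	A	T	synthetic_demo
13940	T	A	synthetic_demo
15101	G	C	synthetic_demo
16220	C	G	synthetic_demo
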