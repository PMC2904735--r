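module_c	toy	C1	C2	C3	C4	C5	C6
short_path	toy	P1	P2	P3
disjoint_edges	toy	A1	A2	B1	B2
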