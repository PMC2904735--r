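source	target
A1	A2
A1	A3
A1	A4
A1	A5
A2	A3
A2	A4
A2	A5
A3	A4
A3	A5
A4	A5
B1	B2
B1	B3
B1	B4
B1	B5
B2	B3
B2	B4
B2	B5
B3	B4
B3	B5
B4	B5
C1	C2
C1	C3
C2	C3
C2	C4
C3	C4
C3	C5
C4	C5
C4	C6
C5	C1
C5	C6
C6	C1
C6	C2
H	L1
H	L2
H	L3
H	L4
H	L5
H	L6
P1	P2
P2	P3
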