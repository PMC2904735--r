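id	z_score	is_kpr
A1	0.5	TRUE
A2	0.5	FALSE
A3	0.5	FALSE
A4	0.5	FALSE
A5	0.5	FALSE
B1	-0.5	FALSE
B2	-0.5	FALSE
B3	-0.5	FALSE
B4	-0.5	FALSE
B5	-0.5	FALSE
C1	2	TRUE
C2	2	FALSE
C3	2	FALSE
C4	2	FALSE
C5	2	FALSE
C6	2	FALSE
H	1.5	FALSE
L1	0	FALSE
L2	0	FALSE
L3	0	FALSE
L4	0	FALSE
L5	0	FALSE
L6	0	FALSE
P1	NA	FALSE
P2	NA	FALSE
P3	NA	FALSE
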