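a1	a2
C1	C2
C1	B4
C1	B6
C1	B10
C1	B12
C2	B4
C2	B5
C2	B9
C2	B12
B3	B4
B3	B5
B3	B6
B3	B7
B3	B8
B4	B5
B4	B6
B5	B7
B5	B9
B6	B8
B6	B10
B7	B8
B7	B9
B7	B11
B8	B10
B8	B11
B9	B11
B9	B12
B10	B11
B10	B12
B11	B12
C1	C3
C3	N1
N1	S
S	O1
S	O2
S	N2
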