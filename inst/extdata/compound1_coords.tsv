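atom	x	y	z
C1	0	0.89	1.4401
C2	0	-0.89	1.4401
B3	-1.4401	0	-0.89
B4	-1.4401	0	0.89
B5	-0.89	-1.4401	0
B6	-0.89	1.4401	0
B7	0	-0.89	-1.4401
B8	0	0.89	-1.4401
B9	0.89	-1.4401	0
B10	0.89	1.4401	0
B11	1.4401	0	-0.89
B12	1.4401	0	0.89
C3	0	1.6891	2.733
N1	0	3.1335	2.4597
S	0	4.1968	3.6951
O1	1.1843	3.9513	4.458
O2	-1.1843	3.9513	4.458
N2	0	5.5955	2.9602
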