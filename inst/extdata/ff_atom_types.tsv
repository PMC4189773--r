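type	epsilon	sigma
CT	0.066	3.6
CR	0.07	3.55
CC	0.066	3.6
B	0.08	3.6
NA	0.17	3.25
OT	0.21	2.96
OH	0.17	3.07
OW	0.152	3.15
S	0.25	3.55
HX	0	1
HP	0	1
HB	0.03	2.6
ZN	0.0125	1.95
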