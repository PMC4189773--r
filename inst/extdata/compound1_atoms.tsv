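res	atom	element	type	charge	hyb	parent	alias
CB1	C1	C	CC	0.08	cage		C1
CB1	C2	C	CC	0	cage		C2
CB1	H2	H	HX	0		C2	H2
CB1	B3	B	B	0.08	cage		B3
CB1	H3	H	HB	-0.08		B3	H3
CB1	B4	B	B	0.08	cage		B4
CB1	H4	H	HB	-0.08		B4	H4
CB1	B5	B	B	0.08	cage		B5
CB1	H5	H	HB	-0.08		B5	H5
CB1	B6	B	B	0.08	cage		B6
CB1	H6	H	HB	-0.08		B6	H6
CB1	B7	B	B	0.08	cage		B7
CB1	H7	H	HB	-0.08		B7	H7
CB1	B8	B	B	0.08	cage		B8
CB1	H8	H	HB	-0.08		B8	H8
CB1	B9	B	B	0.08	cage		B9
CB1	H9	H	HB	-0.08		B9	H9
CB1	B10	B	B	0.08	cage		B10
CB1	H10	H	HB	-0.08		B10	H10
CB1	B11	B	B	0.08	cage		B11
CB1	H11	H	HB	-0.08		B11	H11
CB1	B12	B	B	0.08	cage		B12
CB1	H12	H	HB	-0.08		B12	H12
CB1	C3	C	CT	0.18	sp3		C3
CB1	H31	H	HX	0		C3	H31
CB1	H32	H	HX	0		C3	H32
CB1	N1	N	NA	-0.5	sp3		N1
CB1	HN1	H	HP	0.32		N1	HN1
CB1	S	S	S	1.2	sp3		S
CB1	O1	O	OT	-0.6	sp2		O1
CB1	O2	O	OT	-0.6	sp2		O2
CB1	N2	N	NA	-0.8	sp3		N2
CB1	HN21	H	HP	0.36		N2	HN21
CB1	HN22	H	HP	0.36		N2	HN22
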