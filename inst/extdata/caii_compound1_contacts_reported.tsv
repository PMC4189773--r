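resno	resname	protein_atom	ligand_atom	distance	polar
NA	ZN	ZN	N2	1.87	TRUE
NA	ZN	ZN	S	3.04	FALSE
NA	ZN	ZN	O2	3.05	FALSE
92	GLN	OE1	B6	3.47	FALSE
92	GLN	OE1	B11	3.52	FALSE
92	GLN	CD	B6	3.84	FALSE
94	HIS	CE1	O2	2.97	FALSE
94	HIS	NE2	N2	3.23	FALSE
94	HIS	NE2	O2	3.31	FALSE
94	HIS	CE1	C3	3.67	FALSE
94	HIS	NE2	S	3.81	FALSE
94	HIS	CE1	N2	3.82	FALSE
94	HIS	CE1	S	3.84	FALSE
94	HIS	NE2	C3	3.94	FALSE
96	HIS	NE2	N2	3.14	FALSE
96	HIS	CE1	N2	3.56	FALSE
119	HIS	ND1	N2	3.39	FALSE
119	HIS	ND1	O2	3.88	FALSE
119	HIS	CE1	N2	3.96	FALSE
121	VAL	CG2	O2	3.82	FALSE
131	PHE	CZ	B8	3.83	FALSE
131	PHE	CZ	B7	3.97	FALSE
198	LEU	CA	O1	3.09	FALSE
198	LEU	C	O1	3.36	FALSE
198	LEU	CB	O1	3.60	FALSE
198	LEU	CD2	O1	3.63	FALSE
198	LEU	CD1	B3	3.86	FALSE
199	THR	N	O1	2.70	TRUE
199	THR	OG1	N2	2.74	TRUE
199	THR	OG1	O1	3.58	FALSE
199	THR	OG1	S	3.78	FALSE
199	THR	N	S	3.83	FALSE
199	THR	CA	O1	3.83	FALSE
199	THR	CB	N2	3.98	FALSE
200	THR	OG1	N1	3.02	TRUE
200	THR	OG1	C3	3.14	FALSE
200	THR	OG1	B4	3.36	FALSE
200	THR	OG1	B3	3.56	FALSE
200	THR	OG1	C1	3.66	FALSE
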