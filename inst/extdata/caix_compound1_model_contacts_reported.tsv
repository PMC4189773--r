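resno	resname	protein_atom	ligand_atom	distance	polar
NA	ZN	ZN	N2	2.1	TRUE
NA	ZN	ZN	S	3.3	FALSE
NA	ZN	ZN	O2	3.5	FALSE
5	TRP	CZ2	B5	3.74	FALSE
5	TRP	CZ2	B10	3.81	FALSE
94	HIS	CE1	O2	3.15	FALSE
94	HIS	CE1	C3	3.74	FALSE
94	HIS	NE2	N2	3.36	FALSE
94	HIS	NE2	S	3.88	FALSE
94	HIS	NE2	O2	3.45	FALSE
94	HIS	NE2	C3	3.76	FALSE
96	HIS	CE1	N2	3.99	FALSE
96	HIS	NE2	N2	3.49	FALSE
106	GLU	OE2	N2	3.71	FALSE
119	HIS	ND1	N2	3.37	FALSE
119	HIS	CE1	N2	3.83	FALSE
121	VAL	CG2	O2	3.58	FALSE
198	LEU	CA	O1	3.04	FALSE
198	LEU	CB	O1	3.4	FALSE
198	LEU	CD2	O1	3.43	FALSE
198	LEU	C	O1	3.38	FALSE
199	THR	N	S	3.88	FALSE
199	THR	N	O1	2.79	TRUE
199	THR	CA	O1	3.96	FALSE
199	THR	CB	N2	3.85	FALSE
199	THR	OG1	N2	2.63	TRUE
199	THR	OG1	S	3.69	FALSE
199	THR	OG1	O1	3.65	FALSE
200	THR	OG1	C1	3.77	FALSE
200	THR	OG1	B5	3.56	FALSE
200	THR	OG1	N1	3.13	TRUE
200	THR	OG1	C3	3.31	FALSE
200	THR	OG1	B4	3.64	FALSE
201	PRO	O	B4	3.6	FALSE
201	PRO	O	B10	3.49	FALSE
201	PRO	O	B8	3.96	FALSE
209	TRP	CZ2	O1	3.74	FALSE
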