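res	atom	element	type	charge	hyb	parent
GLY	N	N	NA	-0.47	sp2	
GLY	H	H	HP	0.31		N
GLY	CA	C	CT	0.16	sp3	
GLY	HA2	H	HX	0		CA
GLY	HA3	H	HX	0		CA
GLY	C	C	CR	0.51	sp2	
GLY	O	O	OT	-0.51	sp2	
ALA	N	N	NA	-0.47	sp2	
ALA	H	H	HP	0.31		N
ALA	CA	C	CT	0.16	sp3	
ALA	HA	H	HX	0		CA
ALA	C	C	CR	0.51	sp2	
ALA	O	O	OT	-0.51	sp2	
ALA	CB	C	CT	0	sp3	
ALA	HB1	H	HX	0		CB
ALA	HB2	H	HX	0		CB
ALA	HB3	H	HX	0		CB
VAL	N	N	NA	-0.47	sp2	
VAL	H	H	HP	0.31		N
VAL	CA	C	CT	0.16	sp3	
VAL	HA	H	HX	0		CA
VAL	C	C	CR	0.51	sp2	
VAL	O	O	OT	-0.51	sp2	
VAL	CB	C	CT	0	sp3	
VAL	HB	H	HX	0		CB
VAL	CG1	C	CT	0	sp3	
VAL	HG11	H	HX	0		CG1
VAL	HG12	H	HX	0		CG1
VAL	HG13	H	HX	0		CG1
VAL	CG2	C	CT	0	sp3	
VAL	HG21	H	HX	0		CG2
VAL	HG22	H	HX	0		CG2
VAL	HG23	H	HX	0		CG2
LEU	N	N	NA	-0.47	sp2	
LEU	H	H	HP	0.31		N
LEU	CA	C	CT	0.16	sp3	
LEU	HA	H	HX	0		CA
LEU	C	C	CR	0.51	sp2	
LEU	O	O	OT	-0.51	sp2	
LEU	CB	C	CT	0	sp3	
LEU	HB2	H	HX	0		CB
LEU	HB3	H	HX	0		CB
LEU	CG	C	CT	0	sp3	
LEU	HG	H	HX	0		CG
LEU	CD1	C	CT	0	sp3	
LEU	HD11	H	HX	0		CD1
LEU	HD12	H	HX	0		CD1
LEU	HD13	H	HX	0		CD1
LEU	CD2	C	CT	0	sp3	
LEU	HD21	H	HX	0		CD2
LEU	HD22	H	HX	0		CD2
LEU	HD23	H	HX	0		CD2
ILE	N	N	NA	-0.47	sp2	
ILE	H	H	HP	0.31		N
ILE	CA	C	CT	0.16	sp3	
ILE	HA	H	HX	0		CA
ILE	C	C	CR	0.51	sp2	
ILE	O	O	OT	-0.51	sp2	
ILE	CB	C	CT	0	sp3	
ILE	HB	H	HX	0		CB
ILE	CG1	C	CT	0	sp3	
ILE	HG12	H	HX	0		CG1
ILE	HG13	H	HX	0		CG1
ILE	CG2	C	CT	0	sp3	
ILE	HG21	H	HX	0		CG2
ILE	HG22	H	HX	0		CG2
ILE	HG23	H	HX	0		CG2
ILE	CD1	C	CT	0	sp3	
ILE	HD11	H	HX	0		CD1
ILE	HD12	H	HX	0		CD1
ILE	HD13	H	HX	0		CD1
SER	N	N	NA	-0.47	sp2	
SER	H	H	HP	0.31		N
SER	CA	C	CT	0.16	sp3	
SER	HA	H	HX	0		CA
SER	C	C	CR	0.51	sp2	
SER	O	O	OT	-0.51	sp2	
SER	CB	C	CT	0.23	sp3	
SER	HB2	H	HX	0		CB
SER	HB3	H	HX	0		CB
SER	OG	O	OH	-0.66	sp3	
SER	HG	H	HP	0.43		OG
THR	N	N	NA	-0.47	sp2	
THR	H	H	HP	0.31		N
THR	CA	C	CT	0.16	sp3	
THR	HA	H	HX	0		CA
THR	C	C	CR	0.51	sp2	
THR	O	O	OT	-0.51	sp2	
THR	CB	C	CT	0.23	sp3	
THR	HB	H	HX	0		CB
THR	OG1	O	OH	-0.66	sp3	
THR	HG1	H	HP	0.43		OG1
THR	CG2	C	CT	0	sp3	
THR	HG21	H	HX	0		CG2
THR	HG22	H	HX	0		CG2
THR	HG23	H	HX	0		CG2
CYS	N	N	NA	-0.47	sp2	
CYS	H	H	HP	0.31		N
CYS	CA	C	CT	0.16	sp3	
CYS	HA	H	HX	0		CA
CYS	C	C	CR	0.51	sp2	
CYS	O	O	OT	-0.51	sp2	
CYS	CB	C	CT	0.1	sp3	
CYS	HB2	H	HX	0		CB
CYS	HB3	H	HX	0		CB
CYS	SG	S	S	-0.26	sp3	
CYS	HG	H	HP	0.16		SG
MET	N	N	NA	-0.47	sp2	
MET	H	H	HP	0.31		N
MET	CA	C	CT	0.16	sp3	
MET	HA	H	HX	0		CA
MET	C	C	CR	0.51	sp2	
MET	O	O	OT	-0.51	sp2	
MET	CB	C	CT	0	sp3	
MET	HB2	H	HX	0		CB
MET	HB3	H	HX	0		CB
MET	CG	C	CT	0.06	sp3	
MET	HG2	H	HX	0		CG
MET	HG3	H	HX	0		CG
MET	SD	S	S	-0.12	sp3	
MET	CE	C	CT	0.06	sp3	
MET	HE1	H	HX	0		CE
MET	HE2	H	HX	0		CE
MET	HE3	H	HX	0		CE
PHE	N	N	NA	-0.47	sp2	
PHE	H	H	HP	0.31		N
PHE	CA	C	CT	0.16	sp3	
PHE	HA	H	HX	0		CA
PHE	C	C	CR	0.51	sp2	
PHE	O	O	OT	-0.51	sp2	
PHE	CB	C	CT	0	sp3	
PHE	HB2	H	HX	0		CB
PHE	HB3	H	HX	0		CB
PHE	CG	C	CR	0	ar	
PHE	CD1	C	CR	0	ar	
PHE	HD1	H	HX	0		CD1
PHE	CD2	C	CR	0	ar	
PHE	HD2	H	HX	0		CD2
PHE	CE1	C	CR	0	ar	
PHE	HE1	H	HX	0		CE1
PHE	CE2	C	CR	0	ar	
PHE	HE2	H	HX	0		CE2
PHE	CZ	C	CR	0	ar	
PHE	HZ	H	HX	0		CZ
TYR	N	N	NA	-0.47	sp2	
TYR	H	H	HP	0.31		N
TYR	CA	C	CT	0.16	sp3	
TYR	HA	H	HX	0		CA
TYR	C	C	CR	0.51	sp2	
TYR	O	O	OT	-0.51	sp2	
TYR	CB	C	CT	0	sp3	
TYR	HB2	H	HX	0		CB
TYR	HB3	H	HX	0		CB
TYR	CG	C	CR	0	ar	
TYR	CD1	C	CR	0	ar	
TYR	HD1	H	HX	0		CD1
TYR	CD2	C	CR	0	ar	
TYR	HD2	H	HX	0		CD2
TYR	CE1	C	CR	0	ar	
TYR	HE1	H	HX	0		CE1
TYR	CE2	C	CR	0	ar	
TYR	HE2	H	HX	0		CE2
TYR	CZ	C	CR	0.11	ar	
TYR	OH	O	OH	-0.54	sp3	
TYR	HH	H	HP	0.43		OH
TRP	N	N	NA	-0.47	sp2	
TRP	H	H	HP	0.31		N
TRP	CA	C	CT	0.16	sp3	
TRP	HA	H	HX	0		CA
TRP	C	C	CR	0.51	sp2	
TRP	O	O	OT	-0.51	sp2	
TRP	CB	C	CT	0	sp3	
TRP	HB2	H	HX	0		CB
TRP	HB3	H	HX	0		CB
TRP	CG	C	CR	0	ar	
TRP	CD1	C	CR	0	ar	
TRP	HD1	H	HX	0		CD1
TRP	NE1	N	NA	-0.37	ar	
TRP	HE1	H	HP	0.37		NE1
TRP	CE2	C	CR	0	ar	
TRP	CD2	C	CR	0	ar	
TRP	CE3	C	CR	0	ar	
TRP	HE3	H	HX	0		CE3
TRP	CZ2	C	CR	0	ar	
TRP	HZ2	H	HX	0		CZ2
TRP	CZ3	C	CR	0	ar	
TRP	HZ3	H	HX	0		CZ3
TRP	CH2	C	CR	0	ar	
TRP	HH2	H	HX	0		CH2
ASN	N	N	NA	-0.47	sp2	
ASN	H	H	HP	0.31		N
ASN	CA	C	CT	0.16	sp3	
ASN	HA	H	HX	0		CA
ASN	C	C	CR	0.51	sp2	
ASN	O	O	OT	-0.51	sp2	
ASN	CB	C	CT	0	sp3	
ASN	HB2	H	HX	0		CB
ASN	HB3	H	HX	0		CB
ASN	CG	C	CR	0.55	sp2	
ASN	OD1	O	OT	-0.55	sp2	
ASN	ND2	N	NA	-0.62	sp2	
ASN	HD21	H	HP	0.31		ND2
ASN	HD22	H	HP	0.31		ND2
GLN	N	N	NA	-0.47	sp2	
GLN	H	H	HP	0.31		N
GLN	CA	C	CT	0.16	sp3	
GLN	HA	H	HX	0		CA
GLN	C	C	CR	0.51	sp2	
GLN	O	O	OT	-0.51	sp2	
GLN	CB	C	CT	0	sp3	
GLN	HB2	H	HX	0		CB
GLN	HB3	H	HX	0		CB
GLN	CG	C	CT	0	sp3	
GLN	HG2	H	HX	0		CG
GLN	HG3	H	HX	0		CG
GLN	CD	C	CR	0.55	sp2	
GLN	OE1	O	OT	-0.55	sp2	
GLN	NE2	N	NA	-0.62	sp2	
GLN	HE21	H	HP	0.31		NE2
GLN	HE22	H	HP	0.31		NE2
ASP	N	N	NA	-0.47	sp2	
ASP	H	H	HP	0.31		N
ASP	CA	C	CT	0.16	sp3	
ASP	HA	H	HX	0		CA
ASP	C	C	CR	0.51	sp2	
ASP	O	O	OT	-0.51	sp2	
ASP	CB	C	CT	0.14	sp3	
ASP	HB2	H	HX	0		CB
ASP	HB3	H	HX	0		CB
ASP	CG	C	CR	0.62	sp2	
ASP	OD1	O	OT	-0.88	sp2	
ASP	OD2	O	OT	-0.88	sp2	
GLU	N	N	NA	-0.47	sp2	
GLU	H	H	HP	0.31		N
GLU	CA	C	CT	0.16	sp3	
GLU	HA	H	HX	0		CA
GLU	C	C	CR	0.51	sp2	
GLU	O	O	OT	-0.51	sp2	
GLU	CB	C	CT	0	sp3	
GLU	HB2	H	HX	0		CB
GLU	HB3	H	HX	0		CB
GLU	CG	C	CT	0.14	sp3	
GLU	HG2	H	HX	0		CG
GLU	HG3	H	HX	0		CG
GLU	CD	C	CR	0.62	sp2	
GLU	OE1	O	OT	-0.88	sp2	
GLU	OE2	O	OT	-0.88	sp2	
LYS	N	N	NA	-0.47	sp2	
LYS	H	H	HP	0.31		N
LYS	CA	C	CT	0.16	sp3	
LYS	HA	H	HX	0		CA
LYS	C	C	CR	0.51	sp2	
LYS	O	O	OT	-0.51	sp2	
LYS	CB	C	CT	0	sp3	
LYS	HB2	H	HX	0		CB
LYS	HB3	H	HX	0		CB
LYS	CG	C	CT	0	sp3	
LYS	HG2	H	HX	0		CG
LYS	HG3	H	HX	0		CG
LYS	CD	C	CT	0	sp3	
LYS	HD2	H	HX	0		CD
LYS	HD3	H	HX	0		CD
LYS	CE	C	CT	0.26	sp3	
LYS	HE2	H	HX	0		CE
LYS	HE3	H	HX	0		CE
LYS	NZ	N	NA	-0.25	sp3	
LYS	HZ1	H	HP	0.33		NZ
LYS	HZ2	H	HP	0.33		NZ
LYS	HZ3	H	HP	0.33		NZ
ARG	N	N	NA	-0.47	sp2	
ARG	H	H	HP	0.31		N
ARG	CA	C	CT	0.16	sp3	
ARG	HA	H	HX	0		CA
ARG	C	C	CR	0.51	sp2	
ARG	O	O	OT	-0.51	sp2	
ARG	CB	C	CT	0	sp3	
ARG	HB2	H	HX	0		CB
ARG	HB3	H	HX	0		CB
ARG	CG	C	CT	0	sp3	
ARG	HG2	H	HX	0		CG
ARG	HG3	H	HX	0		CG
ARG	CD	C	CT	0.38	sp3	
ARG	HD2	H	HX	0		CD
ARG	HD3	H	HX	0		CD
ARG	NE	N	NA	-0.7	sp2	
ARG	HE	H	HP	0.44		NE
ARG	CZ	C	CR	0.64	sp2	
ARG	NH1	N	NA	-0.8	sp2	
ARG	HH11	H	HP	0.46		NH1
ARG	HH12	H	HP	0.46		NH1
ARG	NH2	N	NA	-0.8	sp2	
ARG	HH21	H	HP	0.46		NH2
ARG	HH22	H	HP	0.46		NH2
HIS	N	N	NA	-0.47	sp2	
HIS	H	H	HP	0.31		N
HIS	CA	C	CT	0.16	sp3	
HIS	HA	H	HX	0		CA
HIS	C	C	CR	0.51	sp2	
HIS	O	O	OT	-0.51	sp2	
HIS	CB	C	CT	0	sp3	
HIS	HB2	H	HX	0		CB
HIS	HB3	H	HX	0		CB
HIS	CG	C	CR	0.15	ar	
HIS	ND1	N	NA	-0.56	ar	
HIS	CD2	C	CR	0.15	ar	
HIS	HD2	H	HX	0		CD2
HIS	CE1	C	CR	0.3	ar	
HIS	HE1	H	HX	0		CE1
HIS	NE2	N	NA	-0.36	ar	
HIS	HE2	H	HP	0.32		NE2
PRO	N	N	NA	-0.29	sp2	
PRO	CA	C	CT	0.16	sp3	
PRO	HA	H	HX	0		CA
PRO	C	C	CR	0.51	sp2	
PRO	O	O	OT	-0.51	sp2	
PRO	CB	C	CT	0	sp3	
PRO	HB2	H	HX	0		CB
PRO	HB3	H	HX	0		CB
PRO	CG	C	CT	0	sp3	
PRO	HG2	H	HX	0		CG
PRO	HG3	H	HX	0		CG
PRO	CD	C	CT	0.13	sp3	
PRO	HD2	H	HX	0		CD
PRO	HD3	H	HX	0		CD
HOH	O	O	OW	-0.834	sp3	
HOH	H1	H	HP	0.417		O
HOH	H2	H	HP	0.417		O
ZN	ZN	Zn	ZN	2		
LIG	P1	Cl	HP	-1		
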