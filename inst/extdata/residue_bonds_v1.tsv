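resname	a1	a2	order
ALA	N	CA	1
ALA	CA	C	1
ALA	C	O	2
ALA	CA	CB	1
ARG	N	CA	1
ARG	CA	C	1
ARG	C	O	2
ARG	CA	CB	1
ARG	CB	CG	1
ARG	CG	CD	1
ARG	CD	NE	1
ARG	NE	CZ	1
ARG	CZ	NH1	2
ARG	CZ	NH2	1
ASN	N	CA	1
ASN	CA	C	1
ASN	C	O	2
ASN	CA	CB	1
ASN	CB	CG	1
ASN	CG	OD1	2
ASN	CG	ND2	1
ASP	N	CA	1
ASP	CA	C	1
ASP	C	O	2
ASP	CA	CB	1
ASP	CB	CG	1
ASP	CG	OD1	2
ASP	CG	OD2	1
CYS	N	CA	1
CYS	CA	C	1
CYS	C	O	2
CYS	CA	CB	1
CYS	CB	SG	1
GLN	N	CA	1
GLN	CA	C	1
GLN	C	O	2
GLN	CA	CB	1
GLN	CB	CG	1
GLN	CG	CD	1
GLN	CD	OE1	2
GLN	CD	NE2	1
GLU	N	CA	1
GLU	CA	C	1
GLU	C	O	2
GLU	CA	CB	1
GLU	CB	CG	1
GLU	CG	CD	1
GLU	CD	OE1	2
GLU	CD	OE2	1
GLY	N	CA	1
GLY	CA	C	1
GLY	C	O	2
HIS	N	CA	1
HIS	CA	C	1
HIS	C	O	2
HIS	CA	CB	1
HIS	CB	CG	1
HIS	CG	ND1	4
HIS	CG	CD2	4
HIS	ND1	CE1	4
HIS	CD2	NE2	4
HIS	CE1	NE2	4
ILE	N	CA	1
ILE	CA	C	1
ILE	C	O	2
ILE	CA	CB	1
ILE	CB	CG1	1
ILE	CB	CG2	1
ILE	CG1	CD1	1
LEU	N	CA	1
LEU	CA	C	1
LEU	C	O	2
LEU	CA	CB	1
LEU	CB	CG	1
LEU	CG	CD1	1
LEU	CG	CD2	1
LYS	N	CA	1
LYS	CA	C	1
LYS	C	O	2
LYS	CA	CB	1
LYS	CB	CG	1
LYS	CG	CD	1
LYS	CD	CE	1
LYS	CE	NZ	1
MET	N	CA	1
MET	CA	C	1
MET	C	O	2
MET	CA	CB	1
MET	CB	CG	1
MET	CG	SD	1
MET	SD	CE	1
PHE	N	CA	1
PHE	CA	C	1
PHE	C	O	2
PHE	CA	CB	1
PHE	CB	CG	1
PHE	CG	CD1	4
PHE	CG	CD2	4
PHE	CD1	CE1	4
PHE	CD2	CE2	4
PHE	CE1	CZ	4
PHE	CE2	CZ	4
PRO	N	CA	1
PRO	CA	C	1
PRO	C	O	2
PRO	CA	CB	1
PRO	CB	CG	1
PRO	CG	CD	1
PRO	CD	N	1
SER	N	CA	1
SER	CA	C	1
SER	C	O	2
SER	CA	CB	1
SER	CB	OG	1
THR	N	CA	1
THR	CA	C	1
THR	C	O	2
THR	CA	CB	1
THR	CB	OG1	1
THR	CB	CG2	1
TRP	N	CA	1
TRP	CA	C	1
TRP	C	O	2
TRP	CA	CB	1
TRP	CB	CG	1
TRP	CG	CD1	4
TRP	CG	CD2	4
TRP	CD1	NE1	4
TRP	NE1	CE2	4
TRP	CD2	CE2	4
TRP	CD2	CE3	4
TRP	CE3	CZ3	4
TRP	CZ3	CH2	4
TRP	CH2	CZ2	4
TRP	CZ2	CE2	4
TYR	N	CA	1
TYR	CA	C	1
TYR	C	O	2
TYR	CA	CB	1
TYR	CB	CG	1
TYR	CG	CD1	4
TYR	CG	CD2	4
TYR	CD1	CE1	4
TYR	CD2	CE2	4
TYR	CE1	CZ	4
TYR	CE2	CZ	4
TYR	CZ	OH	1
VAL	N	CA	1
VAL	CA	C	1
VAL	C	O	2
VAL	CA	CB	1
VAL	CB	CG1	1
VAL	CB	CG2	1
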