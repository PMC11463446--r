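resname	atomName	element
ALA	N	N
ALA	CA	C
ALA	C	C
ALA	O	O
ALA	CB	C
ARG	N	N
ARG	CA	C
ARG	C	C
ARG	O	O
ARG	CB	C
ARG	CG	C
ARG	CD	C
ARG	NE	N
ARG	CZ	C
ARG	NH1	N
ARG	NH2	N
ASN	N	N
ASN	CA	C
ASN	C	C
ASN	O	O
ASN	CB	C
ASN	CG	C
ASN	OD1	O
ASN	ND2	N
ASP	N	N
ASP	CA	C
ASP	C	C
ASP	O	O
ASP	CB	C
ASP	CG	C
ASP	OD1	O
ASP	OD2	O
CYS	N	N
CYS	CA	C
CYS	C	C
CYS	O	O
CYS	CB	C
CYS	SG	S
GLN	N	N
GLN	CA	C
GLN	C	C
GLN	O	O
GLN	CB	C
GLN	CG	C
GLN	CD	C
GLN	OE1	O
GLN	NE2	N
GLU	N	N
GLU	CA	C
GLU	C	C
GLU	O	O
GLU	CB	C
GLU	CG	C
GLU	CD	C
GLU	OE1	O
GLU	OE2	O
GLY	N	N
GLY	CA	C
GLY	C	C
GLY	O	O
HIS	N	N
HIS	CA	C
HIS	C	C
HIS	O	O
HIS	CB	C
HIS	CG	C
HIS	ND1	N
HIS	CD2	C
HIS	CE1	C
HIS	NE2	N
ILE	N	N
ILE	CA	C
ILE	C	C
ILE	O	O
ILE	CB	C
ILE	CG1	C
ILE	CG2	C
ILE	CD1	C
LEU	N	N
LEU	CA	C
LEU	C	C
LEU	O	O
LEU	CB	C
LEU	CG	C
LEU	CD1	C
LEU	CD2	C
LYS	N	N
LYS	CA	C
LYS	C	C
LYS	O	O
LYS	CB	C
LYS	CG	C
LYS	CD	C
LYS	CE	C
LYS	NZ	N
MET	N	N
MET	CA	C
MET	C	C
MET	O	O
MET	CB	C
MET	CG	C
MET	SD	S
MET	CE	C
PHE	N	N
PHE	CA	C
PHE	C	C
PHE	O	O
PHE	CB	C
PHE	CG	C
PHE	CD1	C
PHE	CD2	C
PHE	CE1	C
PHE	CE2	C
PHE	CZ	C
PRO	N	N
PRO	CA	C
PRO	C	C
PRO	O	O
PRO	CB	C
PRO	CG	C
PRO	CD	C
SER	N	N
SER	CA	C
SER	C	C
SER	O	O
SER	CB	C
SER	OG	O
THR	N	N
THR	CA	C
THR	C	C
THR	O	O
THR	CB	C
THR	OG1	O
THR	CG2	C
TRP	N	N
TRP	CA	C
TRP	C	C
TRP	O	O
TRP	CB	C
TRP	CG	C
TRP	CD1	C
TRP	CD2	C
TRP	NE1	N
TRP	CE2	C
TRP	CE3	C
TRP	CZ2	C
TRP	CZ3	C
TRP	CH2	C
TYR	N	N
TYR	CA	C
TYR	C	C
TYR	O	O
TYR	CB	C
TYR	CG	C
TYR	CD1	C
TYR	CD2	C
TYR	CE1	C
TYR	CE2	C
TYR	CZ	C
TYR	OH	O
VAL	N	N
VAL	CA	C
VAL	C	C
VAL	O	O
VAL	CB	C
VAL	CG1	C
VAL	CG2	C
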