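resname	heavyAtoms
ALA	5
ARG	11
ASN	8
ASP	8
CYS	6
GLN	9
GLU	9
GLY	4
HIS	10
ILE	8
LEU	8
LYS	9
MET	8
PHE	11
PRO	7
SER	6
THR	7
TRP	14
TYR	12
VAL	7
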