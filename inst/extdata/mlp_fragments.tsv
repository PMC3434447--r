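# Atomic lipophilic fragment values keyed by (residue, atom name), with
# element-level fallback rows (residue = *, atom = element symbol).
# SYNTHETIC rule-based values in the spirit of Broto-style atom-level
# fragment schemes (aliphatic/aromatic carbon positive, polar N/O negative,
# sulfur positive, hydrogens via fallback); illustrative data, not a
# published parameter set. Swap this file for a published table via
# read_lipophilic_library(path). Nucleic-acid and sugar atoms resolve
# through the element fallback.
residue	atom	f
ALA	N	-0.55
ALA	CA	0.02
ALA	C	-0.28
ALA	O	-0.40
ALA	OXT	-0.38
ALA	CB	0.63
ARG	N	-0.55
ARG	CA	0.02
ARG	C	-0.28
ARG	O	-0.40
ARG	OXT	-0.38
ARG	CB	0.45
ARG	CG	0.45
ARG	CD	0.45
ARG	NE	-0.65
ARG	CZ	-0.20
ARG	NH1	-0.65
ARG	NH2	-0.65
ASN	N	-0.55
ASN	CA	0.02
ASN	C	-0.28
ASN	O	-0.40
ASN	OXT	-0.38
ASN	CB	0.45
ASN	CG	0.45
ASN	OD1	-0.45
ASN	ND2	-0.60
ASP	N	-0.55
ASP	CA	0.02
ASP	C	-0.28
ASP	O	-0.40
ASP	OXT	-0.38
ASP	CB	0.45
ASP	CG	0.45
ASP	OD1	-0.40
ASP	OD2	-0.40
CYS	N	-0.55
CYS	CA	0.02
CYS	C	-0.28
CYS	O	-0.40
CYS	OXT	-0.38
CYS	CB	0.45
CYS	SG	0.60
GLN	N	-0.55
GLN	CA	0.02
GLN	C	-0.28
GLN	O	-0.40
GLN	OXT	-0.38
GLN	CB	0.45
GLN	CG	0.45
GLN	CD	0.45
GLN	OE1	-0.45
GLN	NE2	-0.60
GLU	N	-0.55
GLU	CA	0.02
GLU	C	-0.28
GLU	O	-0.40
GLU	OXT	-0.38
GLU	CB	0.45
GLU	CG	0.45
GLU	CD	0.45
GLU	OE1	-0.40
GLU	OE2	-0.40
GLY	N	-0.55
GLY	CA	0.02
GLY	C	-0.28
GLY	O	-0.40
GLY	OXT	-0.38
HIS	N	-0.55
HIS	CA	0.02
HIS	C	-0.28
HIS	O	-0.40
HIS	OXT	-0.38
HIS	CB	0.45
HIS	CG	0.31
HIS	ND1	-0.60
HIS	CD2	0.31
HIS	CE1	0.31
HIS	NE2	-0.60
ILE	N	-0.55
ILE	CA	0.02
ILE	C	-0.28
ILE	O	-0.40
ILE	OXT	-0.38
ILE	CB	0.45
ILE	CG1	0.45
ILE	CG2	0.63
ILE	CD1	0.63
LEU	N	-0.55
LEU	CA	0.02
LEU	C	-0.28
LEU	O	-0.40
LEU	OXT	-0.38
LEU	CB	0.45
LEU	CG	0.45
LEU	CD1	0.63
LEU	CD2	0.63
LYS	N	-0.55
LYS	CA	0.02
LYS	C	-0.28
LYS	O	-0.40
LYS	OXT	-0.38
LYS	CB	0.45
LYS	CG	0.45
LYS	CD	0.45
LYS	CE	0.45
LYS	NZ	-0.85
MET	N	-0.55
MET	CA	0.02
MET	C	-0.28
MET	O	-0.40
MET	OXT	-0.38
MET	CB	0.45
MET	CG	0.45
MET	SD	0.60
MET	CE	0.63
PHE	N	-0.55
PHE	CA	0.02
PHE	C	-0.28
PHE	O	-0.40
PHE	OXT	-0.38
PHE	CB	0.45
PHE	CG	0.31
PHE	CD1	0.31
PHE	CD2	0.31
PHE	CE1	0.31
PHE	CE2	0.31
PHE	CZ	0.31
PRO	N	-0.55
PRO	CA	0.02
PRO	C	-0.28
PRO	O	-0.40
PRO	OXT	-0.38
PRO	CB	0.45
PRO	CG	0.45
PRO	CD	0.45
SER	N	-0.55
SER	CA	0.02
SER	C	-0.28
SER	O	-0.40
SER	OXT	-0.38
SER	CB	0.45
SER	OG	-0.45
THR	N	-0.55
THR	CA	0.02
THR	C	-0.28
THR	O	-0.40
THR	OXT	-0.38
THR	CB	0.45
THR	OG1	-0.45
THR	CG2	0.63
TRP	N	-0.55
TRP	CA	0.02
TRP	C	-0.28
TRP	O	-0.40
TRP	OXT	-0.38
TRP	CB	0.45
TRP	CG	0.31
TRP	CD1	0.31
TRP	CD2	0.31
TRP	NE1	-0.60
TRP	CE2	0.31
TRP	CE3	0.31
TRP	CZ2	0.31
TRP	CZ3	0.31
TRP	CH2	0.31
TYR	N	-0.55
TYR	CA	0.02
TYR	C	-0.28
TYR	O	-0.40
TYR	OXT	-0.38
TYR	CB	0.45
TYR	CG	0.31
TYR	CD1	0.31
TYR	CD2	0.31
TYR	CE1	0.31
TYR	CE2	0.31
TYR	CZ	0.31
TYR	OH	-0.45
VAL	N	-0.55
VAL	CA	0.02
VAL	C	-0.28
VAL	O	-0.40
VAL	OXT	-0.38
VAL	CB	0.45
VAL	CG1	0.63
VAL	CG2	0.63
*	C	0.30
*	N	-0.55
*	O	-0.40
*	S	0.60
*	H	0.10
*	P	-0.30
*	F	0.20
*	CL	0.40
*	BR	0.50
*	I	0.60
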