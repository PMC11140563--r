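# All-atom partial charge table for the 20 canonical amino acids (synthetic).
# Package-curated charge set in the CHARMM all-atom style: backbone group
# charges follow the usual amide/carbonyl pattern and side-chain group charges
# are chemically motivated, with every residue summing exactly to its formal
# charge (0 for neutral residues, +1 for Arg/Lys and protonated His, -1 for
# Asp/Glu). Histidine is tabulated only in its doubly protonated (+1) form;
# structures are assumed prepared for pH ~6 where His titrates.
# Atom naming: CHARMM convention (amide hydrogen HN; methylene hydrogens
# HB1/HB2 etc.; Gly alpha hydrogens HA1/HA2).
# Columns: resname, atom, charge (elementary charge units).
resname	atom	charge
ALA	N	-0.47
ALA	HN	0.31
ALA	CA	0.07
ALA	HA	0.09
ALA	C	0.51
ALA	O	-0.51
ALA	CB	-0.27
ALA	HB1	0.09
ALA	HB2	0.09
ALA	HB3	0.09
ARG	N	-0.47
ARG	HN	0.31
ARG	CA	0.07
ARG	HA	0.09
ARG	C	0.51
ARG	O	-0.51
ARG	CB	-0.18
ARG	HB1	0.09
ARG	HB2	0.09
ARG	CG	-0.18
ARG	HG1	0.09
ARG	HG2	0.09
ARG	CD	0.20
ARG	HD1	0.09
ARG	HD2	0.09
ARG	NE	-0.70
ARG	HE	0.44
ARG	CZ	0.64
ARG	NH1	-0.80
ARG	HH11	0.46
ARG	HH12	0.46
ARG	NH2	-0.80
ARG	HH21	0.46
ARG	HH22	0.46
ASN	N	-0.47
ASN	HN	0.31
ASN	CA	0.07
ASN	HA	0.09
ASN	C	0.51
ASN	O	-0.51
ASN	CB	-0.18
ASN	HB1	0.09
ASN	HB2	0.09
ASN	CG	0.55
ASN	OD1	-0.55
ASN	ND2	-0.62
ASN	HD21	0.32
ASN	HD22	0.30
ASP	N	-0.47
ASP	HN	0.31
ASP	CA	0.07
ASP	HA	0.09
ASP	C	0.51
ASP	O	-0.51
ASP	CB	-0.28
ASP	HB1	0.09
ASP	HB2	0.09
ASP	CG	0.62
ASP	OD1	-0.76
ASP	OD2	-0.76
CYS	N	-0.47
CYS	HN	0.31
CYS	CA	0.07
CYS	HA	0.09
CYS	C	0.51
CYS	O	-0.51
CYS	CB	-0.11
CYS	HB1	0.09
CYS	HB2	0.09
CYS	SG	-0.23
CYS	HG1	0.16
GLN	N	-0.47
GLN	HN	0.31
GLN	CA	0.07
GLN	HA	0.09
GLN	C	0.51
GLN	O	-0.51
GLN	CB	-0.18
GLN	HB1	0.09
GLN	HB2	0.09
GLN	CG	-0.18
GLN	HG1	0.09
GLN	HG2	0.09
GLN	CD	0.55
GLN	OE1	-0.55
GLN	NE2	-0.62
GLN	HE21	0.32
GLN	HE22	0.30
GLU	N	-0.47
GLU	HN	0.31
GLU	CA	0.07
GLU	HA	0.09
GLU	C	0.51
GLU	O	-0.51
GLU	CB	-0.18
GLU	HB1	0.09
GLU	HB2	0.09
GLU	CG	-0.28
GLU	HG1	0.09
GLU	HG2	0.09
GLU	CD	0.62
GLU	OE1	-0.76
GLU	OE2	-0.76
GLY	N	-0.47
GLY	HN	0.31
GLY	CA	-0.02
GLY	HA1	0.09
GLY	HA2	0.09
GLY	C	0.51
GLY	O	-0.51
HIS	N	-0.47
HIS	HN	0.31
HIS	CA	0.07
HIS	HA	0.09
HIS	C	0.51
HIS	O	-0.51
HIS	CB	-0.05
HIS	HB1	0.09
HIS	HB2	0.09
HIS	CG	0.19
HIS	ND1	-0.51
HIS	HD1	0.44
HIS	CE1	0.32
HIS	HE1	0.18
HIS	NE2	-0.51
HIS	HE2	0.44
HIS	CD2	0.19
HIS	HD2	0.13
ILE	N	-0.47
ILE	HN	0.31
ILE	CA	0.07
ILE	HA	0.09
ILE	C	0.51
ILE	O	-0.51
ILE	CB	-0.09
ILE	HB	0.09
ILE	CG2	-0.27
ILE	HG21	0.09
ILE	HG22	0.09
ILE	HG23	0.09
ILE	CG1	-0.18
ILE	HG11	0.09
ILE	HG12	0.09
ILE	CD	-0.27
ILE	HD1	0.09
ILE	HD2	0.09
ILE	HD3	0.09
LEU	N	-0.47
LEU	HN	0.31
LEU	CA	0.07
LEU	HA	0.09
LEU	C	0.51
LEU	O	-0.51
LEU	CB	-0.18
LEU	HB1	0.09
LEU	HB2	0.09
LEU	CG	-0.09
LEU	HG	0.09
LEU	CD1	-0.27
LEU	HD11	0.09
LEU	HD12	0.09
LEU	HD13	0.09
LEU	CD2	-0.27
LEU	HD21	0.09
LEU	HD22	0.09
LEU	HD23	0.09
LYS	N	-0.47
LYS	HN	0.31
LYS	CA	0.07
LYS	HA	0.09
LYS	C	0.51
LYS	O	-0.51
LYS	CB	-0.18
LYS	HB1	0.09
LYS	HB2	0.09
LYS	CG	-0.18
LYS	HG1	0.09
LYS	HG2	0.09
LYS	CD	-0.18
LYS	HD1	0.09
LYS	HD2	0.09
LYS	CE	0.21
LYS	HE1	0.05
LYS	HE2	0.05
LYS	NZ	-0.30
LYS	HZ1	0.33
LYS	HZ2	0.33
LYS	HZ3	0.33
MET	N	-0.47
MET	HN	0.31
MET	CA	0.07
MET	HA	0.09
MET	C	0.51
MET	O	-0.51
MET	CB	-0.18
MET	HB1	0.09
MET	HB2	0.09
MET	CG	-0.14
MET	HG1	0.09
MET	HG2	0.09
MET	SD	-0.09
MET	CE	-0.22
MET	HE1	0.09
MET	HE2	0.09
MET	HE3	0.09
PHE	N	-0.47
PHE	HN	0.31
PHE	CA	0.07
PHE	HA	0.09
PHE	C	0.51
PHE	O	-0.51
PHE	CB	-0.18
PHE	HB1	0.09
PHE	HB2	0.09
PHE	CG	0.00
PHE	CD1	-0.115
PHE	HD1	0.115
PHE	CD2	-0.115
PHE	HD2	0.115
PHE	CE1	-0.115
PHE	HE1	0.115
PHE	CE2	-0.115
PHE	HE2	0.115
PHE	CZ	-0.115
PHE	HZ	0.115
PRO	N	-0.29
PRO	CA	0.02
PRO	HA	0.09
PRO	C	0.51
PRO	O	-0.51
PRO	CB	-0.18
PRO	HB1	0.09
PRO	HB2	0.09
PRO	CG	-0.18
PRO	HG1	0.09
PRO	HG2	0.09
PRO	CD	0.00
PRO	HD1	0.09
PRO	HD2	0.09
SER	N	-0.47
SER	HN	0.31
SER	CA	0.07
SER	HA	0.09
SER	C	0.51
SER	O	-0.51
SER	CB	0.05
SER	HB1	0.09
SER	HB2	0.09
SER	OG	-0.66
SER	HG1	0.43
THR	N	-0.47
THR	HN	0.31
THR	CA	0.07
THR	HA	0.09
THR	C	0.51
THR	O	-0.51
THR	CB	0.14
THR	HB	0.09
THR	OG1	-0.66
THR	HG1	0.43
THR	CG2	-0.27
THR	HG21	0.09
THR	HG22	0.09
THR	HG23	0.09
TRP	N	-0.47
TRP	HN	0.31
TRP	CA	0.07
TRP	HA	0.09
TRP	C	0.51
TRP	O	-0.51
TRP	CB	-0.18
TRP	HB1	0.09
TRP	HB2	0.09
TRP	CG	-0.03
TRP	CD1	0.035
TRP	HD1	0.115
TRP	NE1	-0.61
TRP	HE1	0.38
TRP	CE2	0.13
TRP	CD2	-0.02
TRP	CE3	-0.115
TRP	HE3	0.115
TRP	CZ3	-0.115
TRP	HZ3	0.115
TRP	CZ2	-0.115
TRP	HZ2	0.115
TRP	CH2	-0.115
TRP	HH2	0.115
TYR	N	-0.47
TYR	HN	0.31
TYR	CA	0.07
TYR	HA	0.09
TYR	C	0.51
TYR	O	-0.51
TYR	CB	-0.18
TYR	HB1	0.09
TYR	HB2	0.09
TYR	CG	0.00
TYR	CD1	-0.115
TYR	HD1	0.115
TYR	CD2	-0.115
TYR	HD2	0.115
TYR	CE1	-0.115
TYR	HE1	0.115
TYR	CE2	-0.115
TYR	HE2	0.115
TYR	CZ	0.11
TYR	OH	-0.54
TYR	HH	0.43
VAL	N	-0.47
VAL	HN	0.31
VAL	CA	0.07
VAL	HA	0.09
VAL	C	0.51
VAL	O	-0.51
VAL	CB	-0.09
VAL	HB	0.09
VAL	CG1	-0.27
VAL	HG11	0.09
VAL	HG12	0.09
VAL	HG13	0.09
VAL	CG2	-0.27
VAL	HG21	0.09
VAL	HG22	0.09
VAL	HG23	0.09
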