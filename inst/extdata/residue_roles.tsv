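# Interaction role templates for the 20 standard amino acids.
# Columns: res_name, atom_name, roles (comma-separated).
# Roles: apolar, donor, acceptor, cation<g>, anion<g>, ring<g> where <g>
# numbers the group within the residue (ARG guanidinium atoms share cation1;
# TRP carries ring1 = pyrrole and ring2 = benzene).
# Backbone roles use res_name 'ALL' and apply to every standard residue.
# Users can extend this table for nonstandard residues via the
# ifpr.residue_templates option (path to a file in the same format).
res_name	atom_name	roles
ALL	N	donor
ALL	O	acceptor
ALL	OXT	acceptor
ALA	CB	apolar
ARG	CB	apolar
ARG	CG	apolar
ARG	NE	donor,cation1
ARG	NH1	donor,cation1
ARG	NH2	donor,cation1
ARG	CZ	cation1
ASN	CB	apolar
ASN	ND2	donor
ASN	OD1	acceptor
ASP	CB	apolar
ASP	OD1	acceptor,anion1
ASP	OD2	acceptor,anion1
CYS	CB	apolar
CYS	SG	apolar
GLN	CB	apolar
GLN	CG	apolar
GLN	NE2	donor
GLN	OE1	acceptor
GLU	CB	apolar
GLU	CG	apolar
GLU	OE1	acceptor,anion1
GLU	OE2	acceptor,anion1
HIS	CB	apolar
HIS	CG	ring1
HIS	ND1	acceptor,ring1
HIS	CD2	ring1
HIS	CE1	ring1
HIS	NE2	donor,ring1
ILE	CB	apolar
ILE	CG1	apolar
ILE	CG2	apolar
ILE	CD1	apolar
LEU	CB	apolar
LEU	CG	apolar
LEU	CD1	apolar
LEU	CD2	apolar
LYS	CB	apolar
LYS	CG	apolar
LYS	CD	apolar
LYS	NZ	donor,cation1
MET	CB	apolar
MET	CG	apolar
MET	SD	apolar
MET	CE	apolar
PHE	CB	apolar
PHE	CG	apolar,ring1
PHE	CD1	apolar,ring1
PHE	CD2	apolar,ring1
PHE	CE1	apolar,ring1
PHE	CE2	apolar,ring1
PHE	CZ	apolar,ring1
PRO	CB	apolar
PRO	CG	apolar
SER	OG	donor,acceptor
THR	CG2	apolar
THR	OG1	donor,acceptor
TRP	CB	apolar
TRP	CG	apolar,ring1
TRP	CD1	ring1
TRP	NE1	donor,ring1
TRP	CE2	ring1,ring2
TRP	CD2	apolar,ring1,ring2
TRP	CE3	apolar,ring2
TRP	CZ3	apolar,ring2
TRP	CH2	apolar,ring2
TRP	CZ2	apolar,ring2
TYR	CB	apolar
TYR	CG	apolar,ring1
TYR	CD1	apolar,ring1
TYR	CD2	apolar,ring1
TYR	CE1	apolar,ring1
TYR	CE2	apolar,ring1
TYR	CZ	ring1
TYR	OH	donor,acceptor
VAL	CB	apolar
VAL	CG1	apolar
VAL	CG2	apolar
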