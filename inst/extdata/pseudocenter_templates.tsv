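resname	center	kind	center_atoms	v_rule	v_atoms
*	N	DON	N	bisector_opposite	C_prev,CA
*	O	ACC	O	along	C
SER	OG	DAC	OG	along	CB
THR	OG1	DAC	OG1	along	CB
TYR	OH	DAC	OH	along	CZ
CYS	SG	DAC	SG	along	CB
HIS	ND1	DAC	ND1	away_centroid	CG,ND1,CD2,CE1,NE2
HIS	NE2	DAC	NE2	away_centroid	CG,ND1,CD2,CE1,NE2
LYS	NZ	DON	NZ	along	CE
ARG	NE	DON	NE	bisector_opposite	CD,CZ
ARG	NH1	DON	NH1	along	CZ
ARG	NH2	DON	NH2	along	CZ
TRP	NE1	DON	NE1	away_centroid	CG,CD1,NE1,CE2,CD2
ASN	ND2	DON	ND2	along	CG
ASN	OD1	ACC	OD1	along	CG
GLN	NE2	DON	NE2	along	CD
GLN	OE1	ACC	OE1	along	CD
ASP	OD1	ACC	OD1	along	CG
ASP	OD2	ACC	OD2	along	CG
GLU	OE1	ACC	OE1	along	CD
GLU	OE2	ACC	OE2	along	CD
MET	SD	ACC	SD	along	CB
PHE	RING	ARO	CG,CD1,CD2,CE1,CE2,CZ	ring_normal
TYR	RING	ARO	CG,CD1,CD2,CE1,CE2,CZ	ring_normal
HIS	RING	ARO	CG,ND1,CD2,CE1,NE2	ring_normal
TRP	RING5	ARO	CG,CD1,NE1,CE2,CD2	ring_normal
TRP	RING6	ARO	CE2,CD2,CE3,CZ3,CH2,CZ2	ring_normal
ALA	ALI	ALI	CB	none
VAL	ALI	ALI	CB,CG1,CG2	none
LEU	ALI	ALI	CB,CG,CD1,CD2	none
ILE	ALI	ALI	CB,CG1,CG2,CD1	none
PRO	ALI	ALI	CB,CG,CD	none
MET	ALI	ALI	CB,CG,CE	none
LYS	ALI	ALI	CB,CG,CD	none
ARG	ALI	ALI	CB,CG	none
GLU	ALI	ALI	CB,CG	none
GLN	ALI	ALI	CB,CG	none
ASP	ALI	ALI	CB	none
ASN	ALI	ALI	CB	none
THR	ALI	ALI	CG2	none
CYS	ALI	ALI	CB	none
SER	ALI	ALI	CB	none
TRP	ALI	ALI	CB	none
TYR	ALI	ALI	CB	none
PHE	ALI	ALI	CB	none
HIS	ALI	ALI	CB	none
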