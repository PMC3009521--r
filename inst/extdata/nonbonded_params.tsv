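residue_name	atom_name	charge_e	sigma_nm	epsilon_kJmol
ALA	N	-0.570	0.3250	0.7113
ALA	H	0.370	0.1000	0.0000
ALA	CA	0.200	0.3800	0.3349
ALA	C	0.500	0.3750	0.4393
ALA	O	-0.500	0.2960	0.8786
ALA	CB	0.000	0.3910	0.6694
GLY	N	-0.570	0.3250	0.7113
GLY	H	0.370	0.1000	0.0000
GLY	CA	0.200	0.3905	0.4937
GLY	C	0.500	0.3750	0.4393
GLY	O	-0.500	0.2960	0.8786
VAL	N	-0.570	0.3250	0.7113
VAL	H	0.370	0.1000	0.0000
VAL	CA	0.200	0.3800	0.3349
VAL	C	0.500	0.3750	0.4393
VAL	O	-0.500	0.2960	0.8786
VAL	CB	0.000	0.3850	0.3349
VAL	CG1	0.000	0.3910	0.6694
VAL	CG2	0.000	0.3910	0.6694
LEU	N	-0.570	0.3250	0.7113
LEU	H	0.370	0.1000	0.0000
LEU	CA	0.200	0.3800	0.3349
LEU	C	0.500	0.3750	0.4393
LEU	O	-0.500	0.2960	0.8786
LEU	CB	0.000	0.3905	0.4937
LEU	CG	0.000	0.3850	0.3349
LEU	CD1	0.000	0.3910	0.6694
LEU	CD2	0.000	0.3910	0.6694
ILE	N	-0.570	0.3250	0.7113
ILE	H	0.370	0.1000	0.0000
ILE	CA	0.200	0.3800	0.3349
ILE	C	0.500	0.3750	0.4393
ILE	O	-0.500	0.2960	0.8786
ILE	CB	0.000	0.3850	0.3349
ILE	CG1	0.000	0.3905	0.4937
ILE	CG2	0.000	0.3910	0.6694
ILE	CD1	0.000	0.3910	0.6694
PRO	N	-0.570	0.3250	0.7113
PRO	CA	0.200	0.3800	0.3349
PRO	C	0.500	0.3750	0.4393
PRO	O	-0.500	0.2960	0.8786
PRO	CB	0.000	0.3905	0.4937
PRO	CG	0.000	0.3905	0.4937
PRO	CD	0.370	0.3905	0.4937
PHE	N	-0.570	0.3250	0.7113
PHE	H	0.370	0.1000	0.0000
PHE	CA	0.200	0.3800	0.3349
PHE	C	0.500	0.3750	0.4393
PHE	O	-0.500	0.2960	0.8786
PHE	CB	0.000	0.3905	0.4937
PHE	CG	0.000	0.3750	0.4602
PHE	CD1	0.000	0.3750	0.4602
PHE	CD2	0.000	0.3750	0.4602
PHE	CE1	0.000	0.3750	0.4602
PHE	CE2	0.000	0.3750	0.4602
PHE	CZ	0.000	0.3750	0.4602
TRP	N	-0.570	0.3250	0.7113
TRP	H	0.370	0.1000	0.0000
TRP	CA	0.200	0.3800	0.3349
TRP	C	0.500	0.3750	0.4393
TRP	O	-0.500	0.2960	0.8786
TRP	CB	0.000	0.3905	0.4937
TRP	CG	0.000	0.3750	0.4602
TRP	CD1	0.000	0.3750	0.4602
TRP	CD2	0.000	0.3750	0.4602
TRP	NE1	-0.570	0.3250	0.7113
TRP	HE1	0.420	0.1000	0.0000
TRP	CE2	0.150	0.3750	0.4602
TRP	CE3	0.000	0.3750	0.4602
TRP	CZ2	0.000	0.3750	0.4602
TRP	CZ3	0.000	0.3750	0.4602
TRP	CH2	0.000	0.3750	0.4602
MET	N	-0.570	0.3250	0.7113
MET	H	0.370	0.1000	0.0000
MET	CA	0.200	0.3800	0.3349
MET	C	0.500	0.3750	0.4393
MET	O	-0.500	0.2960	0.8786
MET	CB	0.000	0.3905	0.4937
MET	CG	0.235	0.3905	0.4937
MET	SD	-0.470	0.3550	1.0460
MET	CE	0.235	0.3910	0.6694
CYS	N	-0.570	0.3250	0.7113
CYS	H	0.370	0.1000	0.0000
CYS	CA	0.200	0.3800	0.3349
CYS	C	0.500	0.3750	0.4393
CYS	O	-0.500	0.2960	0.8786
CYS	CB	0.180	0.3905	0.4937
CYS	SG	-0.450	0.3550	1.0460
CYS	HG	0.270	0.1000	0.0000
SER	N	-0.570	0.3250	0.7113
SER	H	0.370	0.1000	0.0000
SER	CA	0.200	0.3800	0.3349
SER	C	0.500	0.3750	0.4393
SER	O	-0.500	0.2960	0.8786
SER	CB	0.265	0.3905	0.4937
SER	OG	-0.700	0.3070	0.7113
SER	HG	0.435	0.1000	0.0000
THR	N	-0.570	0.3250	0.7113
THR	H	0.370	0.1000	0.0000
THR	CA	0.200	0.3800	0.3349
THR	C	0.500	0.3750	0.4393
THR	O	-0.500	0.2960	0.8786
THR	CB	0.265	0.3850	0.3349
THR	OG1	-0.700	0.3070	0.7113
THR	HG1	0.435	0.1000	0.0000
THR	CG2	0.000	0.3910	0.6694
TYR	N	-0.570	0.3250	0.7113
TYR	H	0.370	0.1000	0.0000
TYR	CA	0.200	0.3800	0.3349
TYR	C	0.500	0.3750	0.4393
TYR	O	-0.500	0.2960	0.8786
TYR	CB	0.000	0.3905	0.4937
TYR	CG	0.000	0.3750	0.4602
TYR	CD1	0.000	0.3750	0.4602
TYR	CD2	0.000	0.3750	0.4602
TYR	CE1	0.000	0.3750	0.4602
TYR	CE2	0.000	0.3750	0.4602
TYR	CZ	0.150	0.3750	0.4602
TYR	OH	-0.585	0.3070	0.7113
TYR	HH	0.435	0.1000	0.0000
ASN	N	-0.570	0.3250	0.7113
ASN	H	0.370	0.1000	0.0000
ASN	CA	0.200	0.3800	0.3349
ASN	C	0.500	0.3750	0.4393
ASN	O	-0.500	0.2960	0.8786
ASN	CB	0.000	0.3905	0.4937
ASN	CG	0.500	0.3750	0.4393
ASN	OD1	-0.500	0.2960	0.8786
ASN	ND2	-0.850	0.3250	0.7113
ASN	HD21	0.425	0.1000	0.0000
ASN	HD22	0.425	0.1000	0.0000
GLN	N	-0.570	0.3250	0.7113
GLN	H	0.370	0.1000	0.0000
GLN	CA	0.200	0.3800	0.3349
GLN	C	0.500	0.3750	0.4393
GLN	O	-0.500	0.2960	0.8786
GLN	CB	0.000	0.3905	0.4937
GLN	CG	0.000	0.3905	0.4937
GLN	CD	0.500	0.3750	0.4393
GLN	OE1	-0.500	0.2960	0.8786
GLN	NE2	-0.850	0.3250	0.7113
GLN	HE21	0.425	0.1000	0.0000
GLN	HE22	0.425	0.1000	0.0000
ASP	N	-0.570	0.3250	0.7113
ASP	H	0.370	0.1000	0.0000
ASP	CA	0.200	0.3800	0.3349
ASP	C	0.500	0.3750	0.4393
ASP	O	-0.500	0.2960	0.8786
ASP	CB	-0.100	0.3905	0.4937
ASP	CG	0.700	0.3750	0.4393
ASP	OD1	-0.800	0.2960	0.8786
ASP	OD2	-0.800	0.2960	0.8786
GLU	N	-0.570	0.3250	0.7113
GLU	H	0.370	0.1000	0.0000
GLU	CA	0.200	0.3800	0.3349
GLU	C	0.500	0.3750	0.4393
GLU	O	-0.500	0.2960	0.8786
GLU	CB	0.000	0.3905	0.4937
GLU	CG	-0.100	0.3905	0.4937
GLU	CD	0.700	0.3750	0.4393
GLU	OE1	-0.800	0.2960	0.8786
GLU	OE2	-0.800	0.2960	0.8786
LYS	N	-0.570	0.3250	0.7113
LYS	H	0.370	0.1000	0.0000
LYS	CA	0.200	0.3800	0.3349
LYS	C	0.500	0.3750	0.4393
LYS	O	-0.500	0.2960	0.8786
LYS	CB	0.000	0.3905	0.4937
LYS	CG	0.000	0.3905	0.4937
LYS	CD	0.000	0.3905	0.4937
LYS	CE	0.310	0.3905	0.4937
LYS	NZ	-0.300	0.3250	0.7113
LYS	HZ1	0.330	0.1000	0.0000
LYS	HZ2	0.330	0.1000	0.0000
LYS	HZ3	0.330	0.1000	0.0000
ARG	N	-0.570	0.3250	0.7113
ARG	H	0.370	0.1000	0.0000
ARG	CA	0.200	0.3800	0.3349
ARG	C	0.500	0.3750	0.4393
ARG	O	-0.500	0.2960	0.8786
ARG	CB	0.000	0.3905	0.4937
ARG	CG	0.000	0.3905	0.4937
ARG	CD	0.190	0.3905	0.4937
ARG	NE	-0.700	0.3250	0.7113
ARG	HE	0.440	0.1000	0.0000
ARG	CZ	0.830	0.3750	0.4393
ARG	NH1	-0.800	0.3250	0.7113
ARG	HH11	0.460	0.1000	0.0000
ARG	HH12	0.460	0.1000	0.0000
ARG	NH2	-0.800	0.3250	0.7113
ARG	HH21	0.460	0.1000	0.0000
ARG	HH22	0.460	0.1000	0.0000
HIS	N	-0.570	0.3250	0.7113
HIS	H	0.370	0.1000	0.0000
HIS	CA	0.200	0.3800	0.3349
HIS	C	0.500	0.3750	0.4393
HIS	O	-0.500	0.2960	0.8786
HIS	CB	0.000	0.3905	0.4937
HIS	CG	0.150	0.3750	0.4602
HIS	ND1	-0.570	0.3250	0.7113
HIS	HD1	0.420	0.1000	0.0000
HIS	CD2	0.000	0.3750	0.4602
HIS	CE1	0.490	0.3750	0.4602
HIS	NE2	-0.490	0.3250	0.7113
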