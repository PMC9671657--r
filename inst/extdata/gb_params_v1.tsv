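residue	formal_charge	sc_eps	sc_rmin	sc_radius
ALA	0	0.15	2.0	2.0
ARG	1	0.17	3.2	2.9
ASN	0	0.17	2.6	2.5
ASP	-1	0.21	2.6	2.5
CYS	0	0.25	2.3	2.2
GLN	0	0.17	2.8	2.7
GLU	-1	0.21	2.8	2.7
GLY	0	0.00	0.0	0.0
HIS	0	0.17	2.9	2.8
ILE	0	0.15	2.8	2.7
LEU	0	0.15	2.8	2.7
LYS	1	0.17	3.0	2.8
MET	0	0.25	2.9	2.8
PHE	0	0.15	3.1	2.9
PRO	0	0.15	2.5	2.4
SER	0	0.21	2.2	2.1
THR	0	0.21	2.4	2.3
TRP	0	0.15	3.4	3.1
TYR	0	0.17	3.2	3.0
VAL	0	0.15	2.6	2.5
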