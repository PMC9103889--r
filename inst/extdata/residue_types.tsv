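resname	type
ASP	acidic
GLU	acidic
ARG	basic
HIS	basic
LYS	basic
ASN	hydrophilic
CYS	hydrophilic
GLN	hydrophilic
SER	hydrophilic
THR	hydrophilic
ALA	hydrophobic
ILE	hydrophobic
LEU	hydrophobic
MET	hydrophobic
PRO	hydrophobic
VAL	hydrophobic
PHE	aromatic
TRP	aromatic
TYR	aromatic
GLY	excluded
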