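# Unfolded-state cis fractions of Xaa-Pro imide bonds by preceding
# residue Xaa, from model-compound peptide studies (reported range
# roughly 6-38%: aromatic Xaa high, beta-branched aliphatic low).
# Editable: supply a replacement file of the same layout to override,
# e.g. with protein-derived values.
# columns: resid	f_cis
resid	f_cis
ALA	0.16
ARG	0.13
ASN	0.13
ASP	0.12
CYS	0.10
CYS2	0.10
GLN	0.13
GLU	0.12
GLY	0.06
HIS	0.15
ILE	0.10
LEU	0.10
LYS	0.13
MET	0.12
PHE	0.33
PRO	0.12
SER	0.15
THR	0.08
TRP	0.37
TYR	0.24
VAL	0.10
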