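amino_acid,fragment,backbone_indices,C,H,N,O,Si,S
# TBDMS (tert-butyldimethylsilyl) proteinogenic amino acid fragment panel.
# [M-57] loses the tert-butyl radical (C4H9) and retains the full carbon
# backbone; [M-159] additionally loses the silylated carboxyl group
# (C7H15O2Si in total) and hence backbone carbon C1.  The C column counts
# derivatization (non-backbone) carbons only; backbone carbons are given
# by backbone_indices.  Gln/Asn hydrolyze to Glu/Asp during protein
# hydrolysis and are pooled there; Cys and Trp are hydrolysis-labile and
# excluded.
ALA,M-57,1-3,8,26,1,2,2,0
ALA,M-159,2-3,6,20,1,0,1,0
GLY,M-57,1-2,8,24,1,2,2,0
GLY,M-159,2-2,6,18,1,0,1,0
VAL,M-57,1-5,8,30,1,2,2,0
VAL,M-159,2-5,6,24,1,0,1,0
LEU,M-57,1-6,8,32,1,2,2,0
LEU,M-159,2-6,6,26,1,0,1,0
ILE,M-57,1-6,8,32,1,2,2,0
ILE,M-159,2-6,6,26,1,0,1,0
SER,M-57,1-3,14,40,1,3,3,0
SER,M-159,2-3,12,34,1,1,2,0
THR,M-57,1-4,14,42,1,3,3,0
THR,M-159,2-4,12,36,1,1,2,0
ASP,M-57,1-4,14,40,1,4,3,0
ASP,M-159,2-4,12,34,1,2,2,0
GLU,M-57,1-5,14,42,1,4,3,0
GLU,M-159,2-5,12,36,1,2,2,0
PHE,M-57,1-9,8,30,1,2,2,0
PHE,M-159,2-9,6,24,1,0,1,0
TYR,M-57,1-9,14,44,1,3,3,0
TYR,M-159,2-9,12,38,1,1,2,0
PRO,M-57,1-5,8,28,1,2,2,0
PRO,M-159,2-5,6,22,1,0,1,0
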