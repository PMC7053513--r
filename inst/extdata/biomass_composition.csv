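condition,precursor,demand_mmol_per_gCDW
# Synthetic reconstruction of condition-specific biomass precursor demands
# (mmol per g cell dry weight) at the three NaCl anchor concentrations.
# Built from generic Gram-positive biomass composition, scaled so that
# protein/RNA fractions fall and the PHB and free-proline (osmolyte)
# fractions rise with salt.  Values for other NaCl concentrations are
# obtained by interpolation (see interpolate_biomass).
0,ALA,0.44
0,GLY,0.52
0,VAL,0.36
0,LEU,0.39
0,ILE,0.25
0,SER,0.19
0,THR,0.22
0,ASP,0.41
0,PHE,0.16
0,TYR,0.12
0,PRO,0.21
0,GLU,0.70
0,G6P,0.21
0,F6P,0.07
0,R5P,0.60
0,GAP,0.13
0,PG3,0.40
0,PYR,0.30
0,ACCOA,0.90
0,OAA,0.60
0,AKG,0.10
0,PHB,0.70
0.6,ALA,0.42
0.6,GLY,0.49
0.6,VAL,0.34
0.6,LEU,0.37
0.6,ILE,0.24
0.6,SER,0.18
0.6,THR,0.21
0.6,ASP,0.39
0.6,PHE,0.15
0.6,TYR,0.11
0.6,PRO,0.80
0.6,GLU,0.65
0.6,G6P,0.20
0.6,F6P,0.07
0.6,R5P,0.55
0.6,GAP,0.13
0.6,PG3,0.38
0.6,PYR,0.28
0.6,ACCOA,0.85
0.6,OAA,0.55
0.6,AKG,0.09
0.6,PHB,1.67
1.2,ALA,0.37
1.2,GLY,0.44
1.2,VAL,0.31
1.2,LEU,0.33
1.2,ILE,0.21
1.2,SER,0.16
1.2,THR,0.19
1.2,ASP,0.35
1.2,PHE,0.14
1.2,TYR,0.10
1.2,PRO,1.70
1.2,GLU,0.60
1.2,G6P,0.21
1.2,F6P,0.07
1.2,R5P,0.48
1.2,GAP,0.13
1.2,PG3,0.34
1.2,PYR,0.25
1.2,ACCOA,0.80
1.2,OAA,0.50
1.2,AKG,0.08
1.2,PHB,3.43
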