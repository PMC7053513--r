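precursor,nadph_mmol_per_mmol
# Lumped NADPH cost of converting each drained precursor into the biomass
# macromolecules it feeds (nucleotides, lipids, lumped amino acids).
# Costs of explicitly modeled synthesis reactions (amino acids, proline,
# PHB) are carried by those reactions' cofactor coefficients and are
# therefore zero here.
G6P,0
F6P,0
R5P,1.0
GAP,0.3
PG3,1.0
PYR,1.0
ACCOA,1.4
OAA,1.5
AKG,1.0
SER,0
PRO,0
GLU,0.3
PHB,0
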