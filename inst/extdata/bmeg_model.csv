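reaction_id,equation,reversible,kind,cofactors
# --- glucose uptake (PTS) and glycolysis ---
upt,GLC (abcdef) + PEP (ghi) = G6P (abcdef) + PYR (ghi),0,measured,
pgi,G6P (abcdef) = F6P (abcdef),1,free,
pfk,F6P (abcdef) = FBP (abcdef),0,free,ATP:-1
fba,FBP (abcdef) = DHAP (cba) + GAP (def),0,free,
tpi,DHAP (abc) = GAP (abc),0,free,
gap_pg3,GAP (abc) = PG3 (abc),0,free,NADH:1;ATP:1
eno,PG3 (abc) = PEP (abc),0,free,
pyk,PEP (abc) = PYR (abc),0,free,ATP:1
# --- pentose phosphate pathway ---
zwf,G6P (abcdef) = PG6 (abcdef),0,free,NADPH:1
gnd,PG6 (abcdef) = RU5P (bcdef) + CO2 (a),0,free,NADPH:1;CO2:1
rpe,RU5P (abcde) = X5P (abcde),1,free,
rpi,RU5P (abcde) = R5P (abcde),1,free,
tkt1,X5P (abcde) + R5P (fghij) = S7P (abfghij) + GAP (cde),1,free,
tal,S7P (abcdefg) + GAP (hij) = E4P (defg) + F6P (abchij),1,free,
tkt2,X5P (abcde) + E4P (fghi) = F6P (abfghi) + GAP (cde),1,free,
# --- TCA cycle ---
pdh,PYR (abc) = ACCOA (bc) + CO2 (a),0,free,NADH:1;CO2:1
cs,OAA (abcd) + ACCOA (ef) = ICT (dcbfea),0,free,
icd,ICT (abcdef) = AKG (abcde) + CO2 (f),0,free,NADPH:1;CO2:1
akgdh,AKG (abcde) = SUC (bcde) + CO2 (a),0,free,NADH:1;ATP:1;CO2:1
sdh,SUC (abcd) = FUM (abcd) | SUC (abcd) = FUM (dcba),1,free,FADH2:1
fum,FUM (abcd) = MAL (abcd) | FUM (abcd) = MAL (dcba),1,free,
mdh,MAL (abcd) = OAA (abcd),1,free,NADH:1
# --- anaplerosis ---
pepc,PEP (abc) + CO2 (d) = OAA (abcd),0,free,CO2:-1
pyc,PYR (abc) + CO2 (d) = OAA (abcd),0,constrained,ATP:-1;CO2:-1
# --- overflow metabolism and organic acid secretion ---
pox,PYR (abc) = ACE (bc) + CO2 (a),0,constrained,FADH2:1;CO2:1
pta,ACCOA (ab) = ACE (ab),0,free,ATP:1
sec_ace,ACE (ab) = ACEx (ab),0,measured,
ldh,PYR (abc) = LAC (abc),0,measured,NADH:-1
sec_pyr,PYR (abc) = PYRx (abc),0,measured,
sec_suc,SUC (abcd) = SUCx (abcd),0,measured,
sec_akg,AKG (abcde) = AKGx (abcde),0,measured,
# --- glutamate and proline (osmoprotectant) branch ---
gogat,AKG (abcde) = GLU (abcde),0,free,NADPH:-1;ATP:-1
proj,GLU (abcde) = GLU5P (abcde),0,free,ATP:-1
proa,GLU5P (abcde) = GSA (abcde),0,free,NADPH:-1
p5c,GSA (abcde) = P5C (abcde),0,free,
proh,P5C (abcde) = PRO (abcde),0,free,NADPH:-1
# --- polyhydroxybutyrate branch ---
phaa,ACCOA (ab) + ACCOA (cd) = AACOA (abcd),0,free,
phab,AACOA (abcd) = HBCOA (abcd),0,free,NADPH:-1
phac,HBCOA (abcd) = PHB (abcd),0,biomass,
# --- proteinogenic amino acid synthesis (biomass drains with atom maps) ---
syn_ala,PYR (abc) = ALA (abc),0,biomass,NADPH:-1
syn_ser,PG3 (abc) = SER (abc),0,free,NADH:1
syn_gly,SER (abc) = GLY (ab) + C1 (c),0,biomass,
syn_val,PYR (abc) + PYR (def) = VAL (abecf) + CO2 (d),0,biomass,NADPH:-2;CO2:1
syn_leu,PYR (abc) + PYR (def) + ACCOA (gh) = LEU (ghbecf) + CO2 (a) + CO2 (d),0,biomass,NADPH:-2;NADH:1;CO2:2
syn_ile,OAA (abcd) + PYR (efg) = ILE (abfcdg) + CO2 (e),0,biomass,NADPH:-3;ATP:-2;CO2:1
syn_asp,OAA (abcd) = ASP (abcd),0,biomass,NADPH:-1
syn_thr,OAA (abcd) = THR (abcd),0,biomass,NADPH:-3;ATP:-2
syn_phe,PEP (abc) + PEP (def) + E4P (ghij) = PHE (defbcghij) + CO2 (a),0,biomass,NADPH:-2;ATP:-1;CO2:1
syn_tyr,PEP (abc) + PEP (def) + E4P (ghij) = TYR (defbcghij) + CO2 (a),0,biomass,NADPH:-2;ATP:-1;CO2:1;NADH:1
# --- residual biomass precursor drains (untracked sink) ---
bm_ser,SER (abc) = BIOMASS,0,biomass,
bm_pro,PRO (abcde) = BIOMASS,0,biomass,
bm_glu,GLU (abcde) = BIOMASS,0,biomass,
bm_g6p,G6P (abcdef) = BIOMASS,0,biomass,
bm_f6p,F6P (abcdef) = BIOMASS,0,biomass,
bm_r5p,R5P (abcde) = BIOMASS,0,biomass,
bm_gap,GAP (abc) = BIOMASS,0,biomass,
bm_pg3,PG3 (abc) = BIOMASS,0,biomass,
bm_pyr,PYR (abc) = BIOMASS,0,biomass,
bm_accoa,ACCOA (ab) = BIOMASS,0,biomass,
bm_oaa,OAA (abcd) = BIOMASS,0,biomass,
bm_akg,AKG (abcde) = BIOMASS,0,biomass,
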