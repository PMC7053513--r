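---
title: "Models and methods behind osmoflux"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind osmoflux}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

osmoflux implements stationary ¹³C metabolic flux analysis (MFA) for
*Bacillus megaterium* growing on glucose under NaCl stress. This
vignette explains the model, the numerical machinery, the parameters
that matter, and — equally important — what the shipped synthetic data
do and do not demonstrate.

## The metabolic model

The reaction list (`inst/extdata/bmeg_model.csv`) is a reconstruction,
not a published table: it is the smallest atom-mapped network consistent
with the pathways active in this organism under glycolytic growth. It
contains PTS glucose uptake (consuming one PEP per glucose), glycolysis,
the oxidative and non-oxidative pentose phosphate pathway (transketolase
×2, transaldolase), a full TCA cycle, both anaplerotic carboxylases (PEP
carboxylase and pyruvate carboxylase), the pyruvate-oxidase overflow
route next to Pta-AckA acetate secretion, lactate/pyruvate/succinate/
2-oxoglutarate secretion, net glutamate synthesis by GS/GOGAT, the
osmo-adaptive proline branch (glutamate kinase, glutamate-semialdehyde
dehydrogenase, spontaneous cyclization, P5C reductase), and the PHB
branch (PhaA thiolase, NADPH-dependent PhaB reductase, PhaC synthase).
Malic enzyme and the glyoxylate shunt are excluded — there is no
evidence they carry flux here — and acetate is secretion-only, since
*B. megaterium* does not re-import it during batch growth on glucose.

Carbon atoms are 1-based in the conventional biochemical numbering;
atom-map letters are arbitrary but consistent within a reaction.
Succinate and fumarate are symmetric molecules: every reaction touching
them carries two atom-transition variants of weight ½ (`"SUC (abcd) =
FUM (abcd) | SUC (abcd) = FUM (dcba)"`), which makes the pool
distributions orientation-symmetric without special-casing the solver.

CO₂ appears in the atom maps (so each reaction is strictly carbon
balanced and decarboxylation/carboxylation bookkeeping is checked at
load) but is treated as a freely exchanging, unlabeled pool: in an
aerated shake flask the dissolved CO₂ is dominated by gas exchange, so
carboxylases draw effectively unlabeled carbon. This is a deliberate
simplification; transferring the pipeline to poorly aerated cultures
would require balancing the CO₂ pool's labeling.

Untracked drains (`... = BIOMASS`) absorb precursor withdrawal. Twelve
proteinogenic amino acids are modeled explicitly with their standard
precursor atom mappings, because they are the measured species.

## Biomass composition

Precursor demands (mmol · gCDW⁻¹) are anchored at 0, 0.6 and 1.2 M NaCl
and interpolated linearly per precursor in between (constant beyond the
anchors, with a warning). The anchor values are a synthetic
reconstruction: generic Gram-positive protein/RNA/lipid composition at
0 M, with the PHB monomer demand computed from the measured PHB content
(6%, 14.4%, 29.5% of CDW at the three anchors; monomer mass 86 g/mol)
and the free-proline (osmolyte) demand rising steeply with salt. Drain
fluxes in % of uptake follow from balanced growth as
`demand × μ / q_s × 100`.

## Forward model: EMU cascade

Measured fragments are traced backwards through the atom maps; the
resulting elementary metabolite units (EMUs) are grouped by size and
solved as one linear system per size, condensation products entering as
convolutions of strictly smaller EMUs. Reversible reactions contribute
two directed fluxes, `v_fwd = max(v,0) + v_exch` and
`v_bwd = max(-v,0) + v_exch`. A zero total production flux for a needed
EMU is a hard error (it signals a dead end in the flux vector), reported
with the offending EMU. The cascade is validated against an independent
brute-force simulator that iterates the full 2ⁿ isotopomer balance to a
fixed point on toy networks (≤ 6 carbons); agreement is required to
1e-10, and in practice is at machine precision.

Tracers are positional label patterns with molar fractions; 99% 1-¹³C
glucose is modeled as a two-component mixture (99% labeled at C1, 1%
unlabeled), matching the stated chemical purity, and the second
experiment uses 50% U-¹³C/50% U-¹²C glucose.

## Natural-isotope correction

Each TBDMS-derivatized fragment carries its backbone carbons plus a
known derivatization composition (C, H, N, O, Si, S). Column *j* of the
correction matrix is the distribution of observed mass shifts given *j*
backbone ¹³C atoms: the convolution of the natural isotope distributions
of all derivatization atoms and (by default; switchable via
`backbone_natural`) of the remaining backbone carbons. Isotope
abundances are pinned in a versioned table — ¹³C 0.0107, ²⁹Si 0.04685,
³⁰Si 0.03092, etc. — because reproducibility requires pinned constants.
The observation window defaults to backbone+4 mass channels, enough to
capture the silicon tail.

Correction is a bounded non-negative least-squares solve of `C·x ≈ raw`
followed by renormalization (robust to truncated windows), not a direct
inversion. Measurement σ is propagated through the pseudo-inverse to
per-entry skeleton σ; without this propagation the fit's weights would
be miscalibrated by the noise amplification of the correction (the
diagonal of C is ≈ 0.77 for two-silicon fragments), inflating SSR well
above its χ² reference.

The default panel is [M-57] (full backbone) and [M-159] (backbone minus
C1) for Ala, Gly, Val, Leu, Ile, Ser, Thr, Asp, Glu, Phe, Tyr and Pro.
Gln/Asn hydrolyze to Glu/Asp during the 6 M HCl protein hydrolysis and
are pooled there; Cys and Trp are hydrolysis-labile and excluded.

## Inverse problem

The flux space is parametrized by an affine free-flux basis: the null
space of the stoichiometric matrix stacked with the hard constraints
(uptake ≡ 100, constrained reactions, biomass drains), with pivot
reactions chosen by rank-revealing QR so the free parameters are
interpretable fluxes with natural bounds. Measured secretion rates are
*soft* data — they enter the SSR with their σ — rather than hard
constraints, so their uncertainty propagates into the flux intervals.

Two splits are fixed rather than fitted, because glucose-tracer labeling
cannot resolve them: pyruvate carboxylase vs PEP carboxylase (PEP and
pyruvate have identical carbon skeletons in this network, PycA is held
at a minor 2% share consistent with PepC dominance), and pyruvate
oxidase vs Pta-AckA (both produce the same acetate carbons; the Pox
share is fixed per condition). Leaving either free would add an exactly
flat objective direction.

Optimization is bounded Levenberg–Marquardt (`minpack.lm::nls.lm`) on
the residual vector, multi-started (default 20 restarts) from feasible
points sampled around an interior anchor found by minimizing the squared
negativity of irreversible fluxes. Exchange fluxes are fitted as
ξ = v_exch/(100 + v_exch) ∈ [0, 0.99] for bounded, well-conditioned
search. MID σ is floored at 0.003 mol-fraction to keep weights finite.
Degrees of freedom count each fragment MID as its backbone-carbon count
(the distribution is normalized) plus the rate measurements, minus the
fitted parameters. Non-identifiable directions surface as very large
linearized standard errors (`flux_se`), computed from the eigendecomposition
of JᵀJ with flat directions assigned huge, not zero, variance.

Confidence intervals are parametric bootstrap: perturb every measured
MID entry (clip at 0, renormalize) and rate by its σ, refit from the
point estimate, and take 2.5/97.5 percentiles over 200 replicates by
default — a pragmatic trade between percentile stability and runtime.
Calibration is checked by simulation on a one-parameter toy network
where the split ratio is read off a one-carbon fragment: over 200
replicates the empirical coverage of the 95% intervals must lie in
[90%, 99%].

## Cofactor ledger

Supply and demand per cofactor are flux-weighted sums of the signed
reaction coefficients; biosynthetic NADPH demand of the untracked drains
is added from a shipped per-precursor cost table. The NADPH excess,
100·(supply − demand)/demand, is the quantity linking PPP rerouting to
PHB accumulation; by default the demand term includes all consuming
fluxes (proline and PHB synthesis included), and passing
`nadph_costs = NULL` restricts the ledger to explicit reaction
coefficients only. NADPH and NADH pools are kept strictly separate — no
transhydrogenase is modeled — precisely so that "NADPH excess" is
well-defined. Respiratory NADH re-oxidation is outside the carbon
network, so for NADH and FADH₂ only the supply side is meaningful. Net
CO₂ release is the flux-weighted sum of CO₂ coefficients and satisfies
exact carbon closure against uptake, secretion and biomass carbon.

The proline pathway from 2-oxoglutarate costs 3 NADPH (GOGAT, ProA*,
ProH at one each; ProJ consumes ATP only), and each PHB monomer costs 1
(PhaB); both are computed by summing coefficients along the unique
biosynthetic chain, not hard-coded.

## Physiology

Growth rate is the least-squares slope of ln(biomass) vs time over an
explicitly supplied exponential window (no automatic phase detection —
window choice is a judgment call best left visible). Yields are
end-point differences, q_s follows from the balanced-growth identity
q_s = 1000·μ/Y_X/S, and fold changes are rounded half-up to one decimal
to match how such ratios are conventionally reported (62.6/5.8 = 10.793
prints as 10.8; banker's rounding would disagree at exact halves).

## What the synthetic data show — and what they don't

The generator reproduces the study's *conditions*: tabulated μ, yields
and uptake rates per NaCl level, both tracers, additive Gaussian noise
of 0.005 mol-fraction on raw mass fractions (renormalized; matching how
MID σ are reported and weighted, rather than a Dirichlet model) and 3%
relative noise on rates. The true flux vectors are *synthetic*: the free
PPP and overflow fluxes are pinned at documented defaults that rise/fall
with salt in the qualitatively expected direction (zwf 30 → 40 → 55% of
uptake across 0 → 0.6 → 1.2 M). Passing the end-to-end tests therefore
demonstrates that the estimator recovers known truths under realistic
noise — not that the shipped numbers are the organism's fluxes. Real
fitted flux maps, the published NADPH-excess and CO₂-increase figures,
require the study's raw MID measurements, which were not deposited.

Validation problem sizes were chosen to exercise every code path while
staying desk-scale: dual-tracer fits on the full 61-reaction model use
4 restarts; interval calibration uses 200 replicates × 100 bootstrap
samples of the toy network; forward-model cross-checks enumerate all
isotopomers of networks up to 6 carbons.

## Known limitations

* Stationary MFA only: isotopically transient data are out of scope,
  and `check_isotopic_steady_state` exists precisely to justify the
  stationarity assumption from multi-density sampling.
* The CO₂ pool is unlabeled by assumption (see above).
* The biomass composition is a reconstruction; users with measured
  compositions should supply their own anchor table.
* Exchange fluxes are reported but only weakly identified by the two
  glucose tracers; interpret their intervals, not their point values.
* The correction-matrix σ propagation keeps only the diagonal of the
  corrected covariance; residual correlations between mass channels are
  ignored in the SSR weighting.
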