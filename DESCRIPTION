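Package: osmoflux
Title: Stationary 13C Metabolic Flux Analysis of Osmotic-Stress Carbon
    Rerouting in Bacillus megaterium
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for stationary 13C metabolic flux analysis (MFA) of
    central carbon metabolism, built around a carbon-mapped reaction model
    of Bacillus megaterium covering glycolysis, the pentose phosphate
    pathway, the TCA cycle, anaplerosis, overflow metabolism, and the
    proline and polyhydroxybutyrate (PHB) biosynthetic branches. Provides
    an elementary metabolite unit (EMU) simulator of steady-state mass
    isotopomer distributions for arbitrary glucose tracer mixtures,
    natural-isotope correction matrices for TBDMS-derivatized amino acid
    fragments measured by GC-MS, weighted least-squares flux estimation
    with multi-start optimization and Monte-Carlo confidence intervals,
    cofactor (NADPH/NADH/ATP) and CO2 balancing from fitted fluxes,
    growth-physiology statistics, and a synthetic-data generator with
    known ground truth for validating the whole pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    pracma,
    minpack.lm,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
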