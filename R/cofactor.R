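# Cofactor and gas balancing: NADPH/NADH/ATP/FADH2 supply and demand and
# net CO2 release derived from a flux vector via the reactions' cofactor
# coefficients, plus the growth-scaled biosynthetic NADPH demand of the
# untracked biomass drains.

#' Load the per-precursor NADPH cost table
#' @param path CSV with columns `precursor`, `nadph_mmol_per_mmol`.
#' @return named numeric vector keyed by drain reaction id.
#' @export
load_nadph_costs <- function(path = system.file("extdata", "nadph_costs.csv",
                                                package = "osmoflux", mustWork = TRUE)) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, comment.char = "#")
  stats::setNames(df$nadph_mmol_per_mmol, PRECURSOR_REACTION[df$precursor])
}

#' Cofactor ledger of a flux distribution
#'
#' For each cofactor, supply is the flux-weighted sum of positive
#' coefficients, demand the flux-weighted sum of negative coefficients
#' plus (for NADPH) the lumped biosynthetic cost of the untracked biomass
#' drains.  The excess is `100 * (supply - demand) / demand`, the ratio
#' the NADPH-overflow argument rests on.
#'
#' @param network an `mfa_network`.
#' @param fluxes a `flux_vector` (net fluxes used).
#' @param nadph_costs optional named vector of NADPH costs per drain
#'   reaction ([load_nadph_costs()]); set `NULL` to count only explicit
#'   reaction coefficients.
#' @param cofactors which cofactors to tabulate.
#' @return data frame (cofactor, supply, demand, net, excess_percent);
#'   excess is `NA` when demand is zero.
#' @export
cofactor_ledger <- function(network, fluxes, nadph_costs = load_nadph_costs(),
                            cofactors = c("NADPH", "NADH", "ATP", "FADH2", "CO2")) {
  v <- fluxes$net
  supply <- stats::setNames(numeric(length(cofactors)), cofactors)
  demand <- supply
  for (rxn in network$reactions) {
    for (cf in names(rxn$cofactors)) {
      if (!cf %in% cofactors) next
      amt <- rxn$cofactors[[cf]] * v[[rxn$id]]
      if (amt >= 0) supply[cf] <- supply[cf] + amt
      else demand[cf] <- demand[cf] - amt
    }
  }
  if (!is.null(nadph_costs)) {
    for (rid in names(nadph_costs)) {
      if (!rid %in% names(v)) next
      demand["NADPH"] <- demand["NADPH"] + nadph_costs[[rid]] * v[[rid]]
    }
  }
  excess <- ifelse(demand > 0, 100 * (supply - demand) / demand, NA_real_)
  data.frame(cofactor = cofactors, supply = unname(supply), demand = unname(demand),
             net = unname(supply - demand), excess_percent = unname(excess),
             stringsAsFactors = FALSE)
}

# breadth-first path through single-producer chain from a start metabolite
# to a target metabolite, returning the traversed reaction ids
linear_path <- function(network, from, to) {
  producers <- function(met) Filter(function(r)
    any(vapply(r$variants[[1]]$products, `[[`, "", "met") == met), network$reactions)
  path <- character(0)
  met <- to
  visited <- character(0)
  while (met != from) {
    if (met %in% visited) stop("cycle while tracing pathway", call. = FALSE)
    visited <- c(visited, met)
    pr <- producers(met)
    if (!length(pr)) stop(sprintf("path absent: no producer of '%s'", met), call. = FALSE)
    r <- pr[[1]]
    path <- c(r$id, path)
    subs <- vapply(r$variants[[1]]$substrates, `[[`, "", "met")
    met <- subs[1]
  }
  path
}

#' NADPH moles consumed per mole of proline made from 2-oxoglutarate
#'
#' Sums the (negative) NADPH coefficients along the unique biosynthetic
#' chain 2-oxoglutarate -> glutamate -> glutamate-5-phosphate ->
#' glutamate-5-semialdehyde -> pyrroline-5-carboxylate -> proline at unit
#' proline flux.
#'
#' @param network an `mfa_network` containing the proline branch.
#' @return the stoichiometric NADPH count (3 for the shipped model).
#' @export
nadph_per_proline <- function(network) {
  path <- linear_path(network, "AKG", "PRO")
  sum(vapply(path, function(rid) {
    cf <- network$reactions[[rid]]$cofactors
    if ("NADPH" %in% names(cf)) -cf[["NADPH"]] else 0
  }, numeric(1)))
}

#' NADPH moles consumed per PHB monomer from acetyl-CoA
#'
#' @param network an `mfa_network` containing the PhaA/PhaB/PhaC branch.
#' @return the stoichiometric NADPH count (1 for the shipped model).
#' @export
nadph_per_phb_monomer <- function(network) {
  path <- linear_path(network, "ACCOA", "PHB")
  sum(vapply(path, function(rid) {
    cf <- network$reactions[[rid]]$cofactors
    if ("NADPH" %in% names(cf)) -cf[["NADPH"]] else 0
  }, numeric(1)))
}

#' Net CO2 release of a flux distribution
#'
#' Flux-weighted sum of the CO2 cofactor coefficients: decarboxylations
#' minus carboxylations (PEP and pyruvate carboxylase fixation enters
#' negatively).
#'
#' @param network an `mfa_network`.
#' @param fluxes a `flux_vector`.
#' @return net CO2 flux, % of glucose uptake.
#' @export
co2_release <- function(network, fluxes) {
  v <- fluxes$net
  sum(vapply(network$reactions, function(rxn) {
    if ("CO2" %in% names(rxn$cofactors)) rxn$cofactors[["CO2"]] * v[[rxn$id]] else 0
  }, numeric(1)))
}

#' Adenylate energy charge
#'
#' Atkinson's charge `(ATP + 0.5 ADP) / (ATP + ADP + AMP)`.
#'
#' @param atp,adp,amp adenylate pool sizes (any common unit).
#' @return AEC in \[0, 1\].
#' @export
adenylate_energy_charge <- function(atp, adp, amp) {
  stopifnot(atp >= 0, adp >= 0, amp >= 0)
  tot <- atp + adp + amp
  if (tot == 0) stop("all-zero adenylate pools", call. = FALSE)
  (atp + 0.5 * adp) / tot
}
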