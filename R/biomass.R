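# Condition-specific biomass precursor demands and their mapping to the
# model's drain reactions.

# precursor label in the composition table -> model drain reaction
PRECURSOR_REACTION <- c(
  ALA = "syn_ala", GLY = "syn_gly", VAL = "syn_val", LEU = "syn_leu",
  ILE = "syn_ile", SER = "bm_ser", THR = "syn_thr", ASP = "syn_asp",
  PHE = "syn_phe", TYR = "syn_tyr", PRO = "bm_pro", GLU = "bm_glu",
  G6P = "bm_g6p", F6P = "bm_f6p", R5P = "bm_r5p", GAP = "bm_gap",
  PG3 = "bm_pg3", PYR = "bm_pyr", ACCOA = "bm_accoa", OAA = "bm_oaa",
  AKG = "bm_akg", PHB = "phac")

#' Load biomass precursor compositions
#'
#' @param path CSV with columns `condition` (NaCl molarity), `precursor`,
#'   `demand_mmol_per_gCDW`. Defaults to the shipped anchor table at
#'   0, 0.6 and 1.2 M NaCl.
#' @return a `biomass_composition` object: a data frame in long format
#'   with one anchor per condition.
#' @export
load_biomass <- function(path = system.file("extdata", "biomass_composition.csv",
                                            package = "osmoflux", mustWork = TRUE)) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, comment.char = "#")
  if (any(df$demand_mmol_per_gCDW < 0)) stop("biomass demands must be >= 0", call. = FALSE)
  structure(df, class = c("biomass_composition", "data.frame"))
}

#' Interpolate biomass composition to an arbitrary NaCl concentration
#'
#' Piecewise-linear interpolation per precursor between the anchor
#' conditions; beyond the outermost anchors the composition is held
#' constant and a warning is issued.
#'
#' @param compositions a `biomass_composition` with >= 2 anchor conditions.
#' @param nacl NaCl molarity (>= 0) to interpolate at.
#' @return data frame with columns `precursor`, `demand_mmol_per_gCDW`.
#' @export
interpolate_biomass <- function(compositions, nacl) {
  if (!nrow(compositions)) stop("empty anchor list", call. = FALSE)
  stopifnot(nacl >= 0)
  anchors <- sort(unique(compositions$condition))
  if (length(anchors) < 2L) stop("need at least two anchor compositions", call. = FALSE)
  if (nacl < min(anchors) || nacl > max(anchors))
    warning(sprintf("NaCl %.2f M outside anchor range [%g, %g]; using constant extrapolation",
                    nacl, min(anchors), max(anchors)), call. = FALSE)
  precs <- unique(compositions$precursor)
  dem <- vapply(precs, function(p) {
    sub <- compositions[compositions$precursor == p, ]
    sub <- sub[order(sub$condition), ]
    stats::approx(sub$condition, sub$demand_mmol_per_gCDW, xout = nacl, rule = 2)$y
  }, numeric(1))
  data.frame(precursor = precs, demand_mmol_per_gCDW = unname(dem),
             stringsAsFactors = FALSE)
}

#' Convert precursor demands into fixed drain fluxes
#'
#' During balanced exponential growth the drain flux of precursor i is
#' `demand_i * mu / q_s`, expressed here in % of the glucose uptake rate.
#'
#' @param demands data frame from [interpolate_biomass()].
#' @param mu specific growth rate (1/h).
#' @param qs specific glucose uptake rate (mmol/gCDW/h).
#' @return named numeric vector of drain reaction fluxes (% of uptake).
#' @export
biomass_drain_fluxes <- function(demands, mu, qs) {
  stopifnot(mu > 0, qs > 0)
  rid <- PRECURSOR_REACTION[demands$precursor]
  if (anyNA(rid))
    stop(sprintf("unknown precursor(s): %s",
                 paste(demands$precursor[is.na(rid)], collapse = ",")), call. = FALSE)
  stats::setNames(demands$demand_mmol_per_gCDW * mu / qs * 100, rid)
}
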