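# Growth physiology: specific growth rate, yields, specific rates and
# the fold changes derived from them.

#' Load the shipped growth-physiology reference table
#'
#' Specific growth rates, biomass and product yields, specific glucose
#' uptake rates and adenylate energy charge for cultures at 0-1.8 M NaCl.
#'
#' @return data frame (parameter, unit, nacl_M, value, sd).
#' @export
load_physiology_table <- function() {
  utils::read.csv(system.file("extdata", "physiology_table1.csv",
                              package = "osmoflux", mustWork = TRUE),
                  stringsAsFactors = FALSE)
}

#' Look up one value of the physiology table
#' @param tab table from [load_physiology_table()].
#' @param parameter parameter name (`"mu"`, `"Y_XS"`, `"q_s"`,
#'   `"Y_Lactate"`, ...).
#' @param nacl NaCl molarity.
#' @return the value.
#' @export
physiology_value <- function(tab, parameter, nacl) {
  hit <- tab$parameter == parameter & tab$nacl_M == nacl
  if (sum(hit) != 1L) stop(sprintf("no unique entry for %s at %g M", parameter, nacl),
                           call. = FALSE)
  tab$value[hit]
}

#' Specific growth rate from a biomass time course
#'
#' Least-squares slope of `ln(biomass)` against time over the stated
#' exponential-phase window.
#'
#' @param tc data frame with columns `time_h` and `biomass`.
#' @param window numeric length-2 time interval to use; defaults to the
#'   full course.
#' @return list with `mu` (1/h) and `r_squared`.
#' @export
growth_rate <- function(tc, window = range(tc$time_h)) {
  sub <- tc[tc$time_h >= window[1] & tc$time_h <= window[2], ]
  if (nrow(sub) < 3L) stop("window too small: need >= 3 points", call. = FALSE)
  if (any(sub$biomass <= 0)) stop("non-positive biomass in window", call. = FALSE)
  fit <- stats::lm(log(biomass) ~ time_h, data = sub)
  y <- log(sub$biomass)
  tss <- sum((y - mean(y))^2)
  r2 <- if (tss > 0) 1 - sum(stats::residuals(fit)^2) / tss else 1
  list(mu = unname(stats::coef(fit)[2]), r_squared = r2)
}

#' Yields and specific rates from a growth time course
#'
#' Biomass yield `Y_X/S = dX/dS` (gCDW/mol), product yields `Y_P/S`
#' (mmol/mol) from end-point differences over the window, and the
#' specific uptake rate via the balanced-growth identity
#' `q_s = 1000 * mu / Y_X/S`.
#'
#' @param tc data frame with columns `time_h`, `biomass` (gCDW/L),
#'   `glucose_mM`, and optionally `*_mM` product columns.
#' @param window exponential-phase time interval.
#' @return list with `mu`, `Y_XS`, `q_s`, and `Y_PS` (named vector,
#'   mmol/mol) per product column.
#' @export
yields <- function(tc, window = range(tc$time_h)) {
  sub <- tc[tc$time_h >= window[1] & tc$time_h <= window[2], ]
  first <- sub[1, ]; last <- sub[nrow(sub), ]
  dS <- (first$glucose_mM - last$glucose_mM) / 1000  # mol/L
  if (dS <= 0) stop("zero glucose consumption in window", call. = FALSE)
  dX <- last$biomass - first$biomass
  mu <- growth_rate(sub)$mu
  yxs <- dX / dS
  prods <- grep("_mM$", names(tc), value = TRUE)
  prods <- setdiff(prods, "glucose_mM")
  yps <- vapply(prods, function(p) (last[[p]] - first[[p]]) / dS / 1000 * 1000,
                numeric(1))
  names(yps) <- sub("_mM$", "", prods)
  list(mu = mu, Y_XS = yxs, q_s = 1000 * mu / yxs, Y_PS = yps)
}

#' Fold change with half-up rounding to one decimal
#'
#' @param a,b numerator and denominator.
#' @param digits decimals to round to (half-up, matching how one-decimal
#'   fold changes are conventionally reported).
#' @return rounded ratio.
#' @export
fold_change <- function(a, b, digits = 1) {
  if (b == 0) stop("division by zero in fold change", call. = FALSE)
  r <- a / b
  floor(abs(r) * 10^digits + 0.5) / 10^digits * sign(r)
}
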