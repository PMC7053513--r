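# Synthetic tracer-study generator with known ground truth.  The default
# scenarios reproduce the study conditions: Table-1 uptake/secretion
# rates and growth parameters at a given NaCl concentration,
# condition-specific biomass drains, the two glucose tracers (99% 1-13C;
# 50% U-12C/50% U-13C), GC-MS noise of 0.005 mol-fraction on raw mass
# fractions and 3% relative noise on rates.

# condition -> (zwf, pox) defaults: PPP share rises and overflow via
# pyruvate oxidase falls modestly with salt, mimicking the qualitative
# rerouting; these are synthetic choices, not fitted values.
SCENARIO_FREE <- list(`0` = c(zwf = 30, pox = 10),
                      `0.6` = c(zwf = 40, pox = 9),
                      `1.2` = c(zwf = 55, pox = 8))
SCENARIO_EXCHANGE <- c(pgi = 20, rpe = 15, rpi = 15, tkt1 = 5, tal = 5,
                       tkt2 = 5, sdh = 20, fum = 50, mdh = 30)
PYC_DEFAULT <- 2  # % of uptake; PEP carboxylase is the dominant anaplerotic route

# secretion reaction -> physiology-table yield parameter
RATE_PARAMS <- c(sec_ace = "Y_Acetate", ldh = "Y_Lactate", sec_pyr = "Y_Pyruvate",
                 sec_suc = "Y_Succinate", sec_akg = "Y_Oxoglutarate")

#' Measured secretion rates for a condition, in % of glucose uptake
#'
#' Converts the physiology table's product yields (mmol per mol glucose)
#' into fluxes relative to uptake = 100.
#'
#' @param nacl NaCl molarity present in the table.
#' @param rel_sd relative standard deviation attached to each rate.
#' @return data frame (reaction, value, sd).
#' @export
condition_rates <- function(nacl, rel_sd = 0.03) {
  tab <- load_physiology_table()
  val <- vapply(RATE_PARAMS, function(p) physiology_value(tab, p, nacl) / 10,
                numeric(1))
  data.frame(reaction = names(RATE_PARAMS), value = unname(val),
             sd = pmax(unname(val) * rel_sd, 0.02), stringsAsFactors = FALSE)
}

#' Build a synthetic tracer-study scenario with known true fluxes
#'
#' Assembles the shipped network, the condition's biomass drains and
#' secretion rates, and a fully determined true flux vector (the free
#' pentose-phosphate and pyruvate-oxidase fluxes pinned at documented
#' defaults), plus tracer definitions and noise levels.
#'
#' @param nacl condition, one of 0, 0.6, 1.2 M NaCl.
#' @param mid_sd additive Gaussian noise on raw mass fractions.
#' @param rate_rel_sd relative noise on rate measurements.
#' @param seed RNG seed recorded in the scenario.
#' @return an `mfa_scenario`.
#' @export
osmoflux_scenario <- function(nacl = 0, mid_sd = 0.005, rate_rel_sd = 0.03,
                              seed = 1L) {
  network <- bmeg_network()
  fragments <- load_fragment_table()
  tab <- load_physiology_table()
  mu <- physiology_value(tab, "mu", nacl)
  qs <- physiology_value(tab, "q_s", nacl)
  demands <- interpolate_biomass(load_biomass(), nacl)
  drains <- biomass_drain_fluxes(demands, mu, qs)
  rates <- condition_rates(nacl, rate_rel_sd)
  key <- as.character(nacl)
  if (!key %in% names(SCENARIO_FREE))
    stop(sprintf("no scenario defaults for %g M NaCl", nacl), call. = FALSE)
  free <- SCENARIO_FREE[[key]]
  fixed <- c(stats::setNames(100, network$uptake_reaction),
             pyc = PYC_DEFAULT, pox = unname(free["pox"]), drains)
  # truth: pin the secretions and the PPP flux as well -> unique vector
  fixed_truth <- c(fixed, stats::setNames(rates$value, rates$reaction),
                   zwf = unname(free["zwf"]))
  basis <- free_flux_basis(network, fixed_truth)
  if (basis$dim != 0)
    stop(sprintf("scenario under-determined: %d residual degrees of freedom", basis$dim),
         call. = FALSE)
  truth <- flux_vector(basis$v0, SCENARIO_EXCHANGE)
  irrev <- !vapply(network$reactions, `[[`, TRUE, "reversible")
  if (any(truth$net[irrev] < -1e-8))
    stop("scenario infeasible: negative irreversible flux in truth", call. = FALSE)
  structure(list(network = network, fragments = fragments, nacl = nacl,
                 truth = truth, fixed = fixed, rates = rates,
                 tracers = list(c1 = tracer_1c13(), u50 = tracer_u13c50()),
                 mid_sd = mid_sd, rate_rel_sd = rate_rel_sd,
                 mu = mu, qs = qs, seed = seed),
            class = "mfa_scenario")
}

#' @export
print.mfa_scenario <- function(x, ...) {
  cat(sprintf("mfa_scenario: %g M NaCl, mu=%.2f 1/h, q_s=%.1f mmol/gCDW/h, mid_sd=%.3f\n",
              x$nacl, x$mu, x$qs, x$mid_sd))
  invisible(x)
}

#' Sample a feasible balanced flux vector
#'
#' Draws the free fluxes uniformly within bounds, maps them through the
#' free-flux basis and rejects draws violating irreversibility.
#'
#' @param network an `mfa_network`.
#' @param fixed named fixed rates as in [free_flux_basis()].
#' @param seed RNG seed.
#' @param lower,upper bounds for free fluxes (recycled).
#' @param max_tries rejection budget.
#' @return a `flux_vector` (exchange fluxes zero).
#' @export
sample_feasible_fluxes <- function(network, fixed, seed = 1L,
                                   lower = 0, upper = 80, max_tries = 5000L) {
  set.seed(seed)
  basis <- free_flux_basis(network, fixed)
  irrev <- !vapply(network$reactions, `[[`, TRUE, "reversible")
  if (basis$dim == 0) {
    v <- basis$v0
    if (any(v[irrev] < -1e-8)) stop("infeasible constraints", call. = FALSE)
    return(flux_vector(v))
  }
  lo <- rep_len(lower, basis$dim); hi <- rep_len(upper, basis$dim)
  free_irrev <- irrev[basis$free_ids]
  lo[free_irrev] <- pmax(lo[free_irrev], 0)
  for (i in seq_len(max_tries)) {
    t <- stats::runif(basis$dim, lo, hi)
    v <- flux_from_free(basis, stats::setNames(t, basis$free_ids))
    if (all(v[irrev] >= -1e-9)) return(flux_vector(v))
  }
  stop("rejection budget exceeded while sampling feasible fluxes", call. = FALSE)
}

#' Generate one noisy tracer experiment from a scenario
#'
#' Simulates the carbon-skeleton MIDs of the fragment panel under the
#' true fluxes, applies natural isotopes (the generator's forward use of
#' the correction matrices), adds additive Gaussian noise to the raw mass
#' fractions (clipped at zero, renormalized), and perturbs the rate
#' measurements multiplicatively.
#'
#' @param scenario an `mfa_scenario`.
#' @param tracer `"c1"` or `"u50"`, or a `tracer_mixture`.
#' @param seed RNG seed (deterministic output per seed).
#' @return list with `mids` (data frame: fragment_id, mass_shift,
#'   fraction, sd), `rates` (data frame), and the tracer used.
#' @export
generate_tracer_experiment <- function(scenario, tracer = "c1", seed = scenario$seed) {
  set.seed(seed)
  if (is.character(tracer)) tracer <- scenario$tracers[[tracer]]
  net <- scenario$network
  emu <- emu_decompose(net, fragment_targets(scenario$fragments))
  sk <- simulate_fragment_mids(net, emu, scenario$truth, tracer, scenario$fragments)
  abund <- load_isotope_table()
  rows <- list()
  for (i in seq_len(nrow(scenario$fragments))) {
    frag <- scenario$fragments[i, ]
    C <- correction_matrix(frag, abund)
    raw <- uncorrect_mid(sk[[frag$fragment_id]], C)
    noisy <- pmax(raw + stats::rnorm(length(raw), 0, scenario$mid_sd), 0)
    noisy <- noisy / sum(noisy)
    rows[[i]] <- data.frame(fragment_id = frag$fragment_id,
                            mass_shift = seq_along(raw) - 1L,
                            fraction = noisy, sd = scenario$mid_sd,
                            stringsAsFactors = FALSE)
  }
  rates <- scenario$rates
  rates$value <- rates$value * (1 + stats::rnorm(nrow(rates), 0, scenario$rate_rel_sd))
  list(mids = do.call(rbind, rows), rates = rates, tracer = tracer)
}

#' Build a flux estimation problem from generated experiments
#'
#' Corrects each experiment's raw MIDs back to carbon-skeleton space
#' (propagating measurement uncertainty) and assembles an [mfa_problem()]
#' with the scenario's hard constraints and soft rate measurements.
#'
#' @param scenario an `mfa_scenario`.
#' @param experiments list of outputs of [generate_tracer_experiment()].
#' @param settings optimizer settings passed to [mfa_problem()].
#' @return an `mfa_problem`.
#' @export
scenario_problem <- function(scenario, experiments, settings = list()) {
  abund <- load_isotope_table()
  exps <- lapply(experiments, function(ex) {
    mids <- list()
    for (i in seq_len(nrow(scenario$fragments))) {
      frag <- scenario$fragments[i, ]
      sub <- ex$mids[ex$mids$fragment_id == frag$fragment_id, ]
      if (!nrow(sub)) next
      C <- correction_matrix(frag, abund)
      corr <- correct_mid(sub$fraction[order(sub$mass_shift)], C,
                          sd = sub$sd[order(sub$mass_shift)])
      mids[[frag$fragment_id]] <- list(mid = corr$mid, sd = corr$sd)
    }
    list(tracer = ex$tracer, mids = mids)
  })
  rates <- experiments[[1]]$rates
  mfa_problem(scenario$network, scenario$fragments, exps, rates,
              scenario$fixed, settings)
}

#' Generate a synthetic growth time course
#'
#' Exponential biomass growth at the condition's growth rate, glucose
#' depletion according to the biomass yield, product accumulation
#' according to the product yields, with multiplicative Gaussian noise.
#'
#' @param nacl condition (must exist in the physiology table).
#' @param hours duration; sampled every `dt` hours.
#' @param dt sampling interval (h).
#' @param x0 inoculum biomass (gCDW/L).
#' @param s0 initial glucose (mM).
#' @param noise multiplicative noise sd (0 = exact).
#' @param seed RNG seed.
#' @param mu,yxs overrides for the growth rate (1/h) and biomass yield
#'   (gCDW/mol); default to the condition's tabulated values.
#' @return data frame (time_h, biomass, glucose_mM, acetate_mM,
#'   lactate_mM, pyruvate_mM, succinate_mM, oxoglutarate_mM).
#' @export
generate_growth_timecourse <- function(nacl = 0, hours = 3, dt = 0.25,
                                       x0 = 0.05, s0 = 27.8, noise = 0.05,
                                       seed = 1L, mu = NULL, yxs = NULL) {
  set.seed(seed)
  tab <- load_physiology_table()
  if (is.null(mu)) mu <- physiology_value(tab, "mu", nacl)
  if (mu <= 0) stop("growth rate must be positive", call. = FALSE)
  if (is.null(yxs)) yxs <- physiology_value(tab, "Y_XS", nacl)
  t <- seq(0, hours, by = dt)
  x <- x0 * exp(mu * t)
  consumed_mM <- (x - x0) / yxs * 1000
  s <- pmax(s0 - consumed_mM, 0)
  prods <- c(acetate = "Y_Acetate", lactate = "Y_Lactate", pyruvate = "Y_Pyruvate",
             succinate = "Y_Succinate", oxoglutarate = "Y_Oxoglutarate")
  out <- data.frame(time_h = t,
                    biomass = x * (1 + stats::rnorm(length(t), 0, noise)),
                    glucose_mM = s * (1 + stats::rnorm(length(t), 0, noise)))
  for (p in names(prods)) {
    y <- physiology_value(tab, prods[[p]], nacl) / 1000  # mmol product per mmol glc
    out[[paste0(p, "_mM")]] <- consumed_mM * y * (1 + stats::rnorm(length(t), 0, noise))
  }
  if (noise == 0) out$biomass <- x  # avoid -0 artifacts
  out
}
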