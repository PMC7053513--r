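# Weighted least-squares flux estimation.  Net fluxes are parametrized
# through an affine free-flux basis (null space of the stoichiometric
# constraints plus fixed rates); exchange fluxes of reversible reactions
# through the bounded transform xi = v_exch / (scale + v_exch).

EXCHANGE_SCALE <- 100   # % of glucose uptake
SIGMA_FLOOR <- 0.003    # mol-fraction floor on MID standard deviations

#' Free-flux parametrization of the balanced flux space
#'
#' Computes an affine map from a small set of interpretable free fluxes
#' (picked as well-conditioned pivot reactions of the null space) to full,
#' stoichiometrically balanced flux vectors satisfying the fixed rates.
#'
#' @param network an `mfa_network`.
#' @param fixed named numeric vector of fixed reaction rates (% of
#'   uptake); typically the uptake normalization, constrained reactions
#'   and biomass drains.
#' @return a `flux_basis`: list with `free_ids`, `v0` (particular
#'   solution), `M` (map matrix), and `dim`.
#' @export
free_flux_basis <- function(network, fixed) {
  S <- stoichiometric_matrix(network)
  ids <- colnames(S)
  bad <- setdiff(names(fixed), ids)
  if (length(bad)) stop(sprintf("fixed rate(s) for unknown reaction(s): %s",
                                paste(bad, collapse = ",")), call. = FALSE)
  E <- matrix(0, length(fixed), length(ids), dimnames = list(names(fixed), ids))
  E[cbind(seq_along(fixed), match(names(fixed), ids))] <- 1
  A <- rbind(S, E)
  b <- c(numeric(nrow(S)), unname(fixed))
  sv <- svd(A, nv = ncol(A))
  tol <- max(dim(A)) * max(sv$d) * .Machine$double.eps
  r <- sum(sv$d > tol)
  # minimum-norm particular solution
  v0 <- sv$v[, seq_len(r), drop = FALSE] %*%
    ((t(sv$u[, seq_len(r), drop = FALSE]) %*% b) / sv$d[seq_len(r)])
  v0 <- stats::setNames(as.vector(v0), ids)
  resid <- A %*% v0 - b
  if (max(abs(resid)) > 1e-7) {
    worst <- rownames(A)[which.max(abs(resid))]
    stop(sprintf("infeasible fixed rates: constraint '%s' violated by %.3g",
                 worst, max(abs(resid))), call. = FALSE)
  }
  d <- ncol(A) - r
  if (d == 0) {
    return(structure(list(free_ids = character(0), v0 = v0,
                          M = matrix(0, length(ids), 0, dimnames = list(ids, NULL)),
                          dim = 0L), class = "flux_basis"))
  }
  N <- sv$v[, (r + 1):ncol(sv$v), drop = FALSE]
  rownames(N) <- ids
  # pick d pivot reactions whose rows of N are maximally independent
  piv <- qr(t(N), LAPACK = TRUE)$pivot[seq_len(d)]
  P <- N[piv, , drop = FALSE]
  M <- N %*% solve(P)
  colnames(M) <- ids[piv]
  structure(list(free_ids = ids[piv], v0 = v0, M = M, dim = d),
            class = "flux_basis")
}

#' @export
print.flux_basis <- function(x, ...) {
  cat(sprintf("flux_basis: %d free flux(es): %s\n", x$dim,
              paste(x$free_ids, collapse = ", ")))
  invisible(x)
}

#' Map free-flux values to a full balanced net flux vector
#' @param basis a `flux_basis`.
#' @param free named (or ordered) values of the free fluxes.
#' @return named numeric net flux vector over all reactions.
#' @export
flux_from_free <- function(basis, free) {
  if (basis$dim == 0) return(basis$v0)
  if (!is.null(names(free))) free <- free[basis$free_ids]
  as.vector(basis$v0 + basis$M %*% (free - basis$v0[basis$free_ids])) |>
    stats::setNames(names(basis$v0))
}

#' Assemble a flux estimation problem
#'
#' @param network an `mfa_network`.
#' @param fragments fragment table ([load_fragment_table()]).
#' @param experiments list of tracer experiments, each a list with
#'   `tracer` (a `tracer_mixture`) and `mids`: a named list of
#'   `list(mid=, sd=)` carbon-skeleton measurements per `fragment_id`.
#' @param rates data frame with columns `reaction`, `value`, `sd`
#'   (% of uptake) entering the objective as soft measurements.
#' @param fixed named vector of hard-fixed rates (uptake = 100,
#'   constrained reactions, biomass drains).
#' @param settings optimizer settings: `restarts`, `seed`, `maxiter`,
#'   `n_monte_carlo`.
#' @return an `mfa_problem`.
#' @export
mfa_problem <- function(network, fragments, experiments, rates, fixed,
                        settings = list()) {
  defaults <- list(restarts = 20L, seed = 1L, maxiter = 60L, n_monte_carlo = 200L)
  settings <- utils::modifyList(defaults, settings)
  basis <- free_flux_basis(network, fixed)
  emu <- emu_decompose(network, fragment_targets(fragments))
  for (ex in experiments)
    for (fid in names(ex$mids))
      if (!fid %in% fragments$fragment_id)
        stop(sprintf("measured fragment '%s' not in panel", fid), call. = FALSE)
  if (!is.null(rates) && nrow(rates)) {
    bad <- setdiff(rates$reaction, names(network$reactions))
    if (length(bad)) stop(sprintf("rate measurement for unknown reaction(s): %s",
                                  paste(bad, collapse = ",")), call. = FALSE)
    if (any(rates$sd <= 0)) stop("rate sd must be > 0", call. = FALSE)
  }
  rev_ids <- names(network$reactions)[vapply(network$reactions, `[[`, TRUE, "reversible")]
  structure(list(network = network, fragments = fragments, emu = emu,
                 experiments = experiments, rates = rates, fixed = fixed,
                 basis = basis, exchange_ids = rev_ids, settings = settings),
            class = "mfa_problem")
}

problem_par_info <- function(problem) {
  basis <- problem$basis
  net <- problem$network
  irrev <- !vapply(net$reactions, `[[`, TRUE, "reversible")
  lo <- ifelse(irrev[basis$free_ids], 0, -300)
  hi <- rep(300, basis$dim)
  nx <- length(problem$exchange_ids)
  list(n_free = basis$dim, n_exch = nx,
       lower = c(lo, rep(0, nx)), upper = c(hi, rep(0.99, nx)),
       names = c(basis$free_ids,
                 if (nx) paste0("xi_", problem$exchange_ids) else character(0)))
}

params_to_fluxes <- function(problem, params) {
  d <- problem$basis$dim
  net <- flux_from_free(problem$basis, stats::setNames(params[seq_len(d)],
                                                       problem$basis$free_ids))
  xi <- params[d + seq_along(problem$exchange_ids)]
  exch <- EXCHANGE_SCALE * xi / (1 - xi)
  flux_vector(net, stats::setNames(exch, problem$exchange_ids))
}

problem_residuals <- function(problem, params, penalty_weight = 1e3) {
  fl <- params_to_fluxes(problem, params)
  net <- problem$network
  irrev <- !vapply(net$reactions, `[[`, TRUE, "reversible")
  pen <- pmin(fl$net[irrev], 0) * penalty_weight
  res <- as.numeric(pen)
  nms <- paste0("pen_", names(fl$net)[irrev])
  # simulate with irreversible fluxes clipped at zero so the EMU systems
  # stay defined while the penalty residuals push the iterate back
  fl_sim <- fl
  fl_sim$net[irrev] <- pmax(fl_sim$net[irrev], 0)
  sim_fail <- FALSE
  for (e in seq_along(problem$experiments)) {
    ex <- problem$experiments[[e]]
    sims <- tryCatch(
      simulate_fragment_mids(net, problem$emu, fl_sim, ex$tracer, problem$fragments),
      error = function(err) NULL)
    if (is.null(sims)) { sim_fail <- TRUE; break }
    for (fid in names(ex$mids)) {
      meas <- ex$mids[[fid]]
      sd <- pmax(meas$sd, SIGMA_FLOOR)
      r <- (sims[[fid]] - meas$mid) / sd
      res <- c(res, r)
      nms <- c(nms, paste0("ex", e, "_", fid, "_M", seq_along(r) - 1L))
    }
  }
  if (sim_fail) {
    n <- n_measurements(problem) + sum(irrev)
    return(stats::setNames(rep(1e6, n), rep("simulation_failure", n)))
  }
  if (!is.null(problem$rates) && nrow(problem$rates)) {
    r <- (fl$net[problem$rates$reaction] - problem$rates$value) / problem$rates$sd
    res <- c(res, r)
    nms <- c(nms, paste0("rate_", problem$rates$reaction))
  }
  stats::setNames(res, nms)
}

n_measurements <- function(problem) {
  n <- 0L
  for (ex in problem$experiments)
    for (m in ex$mids) n <- n + length(m$mid)
  n + if (is.null(problem$rates)) 0L else nrow(problem$rates)
}

#' Weighted sum of squared residuals of a parameter vector
#'
#' `SSR = sum(((sim - meas)/sd)^2)` over all MID entries of all tracer
#' experiments plus all rate measurements.
#'
#' @param problem an `mfa_problem`.
#' @param params numeric vector: free fluxes followed by exchange
#'   parameters `xi` in `[0, 0.99)`.
#' @return the scalar SSR.
#' @export
objective <- function(problem, params) {
  sum(problem_residuals(problem, params)^2)
}

#' Degrees of freedom of the fit
#'
#' Independent measurements (each fragment MID contributes its backbone
#' carbon count, since the distribution is normalized) minus fitted
#' parameters.
#'
#' @param problem an `mfa_problem`.
#' @return integer degrees of freedom.
#' @export
problem_dof <- function(problem) {
  n <- 0L
  for (ex in problem$experiments)
    for (m in ex$mids) n <- n + length(m$mid) - 1L
  n <- n + if (is.null(problem$rates)) 0L else nrow(problem$rates)
  n - problem$basis$dim - length(problem$exchange_ids)
}

# a feasible interior point of the free-flux polytope, found by driving
# the squared negativity of irreversible fluxes to zero (the map from
# free fluxes to the full vector is affine, so this is smooth and cheap)
feasible_anchor <- function(problem) {
  basis <- problem$basis
  irrev <- !vapply(problem$network$reactions, `[[`, TRUE, "reversible")
  slack <- 1
  negpen <- function(t) {
    v <- flux_from_free(basis, stats::setNames(t, basis$free_ids))
    sum(pmin(v[irrev] - slack, 0)^2)
  }
  t0 <- basis$v0[basis$free_ids]
  if (!is.null(problem$rates)) {
    hit <- match(basis$free_ids, problem$rates$reaction)
    t0[!is.na(hit)] <- problem$rates$value[hit[!is.na(hit)]]
  }
  opt <- stats::optim(t0, negpen, method = "BFGS",
                      control = list(maxit = 200, reltol = 1e-12))
  opt$par
}

random_start <- function(problem, info, anchor) {
  d <- info$n_free
  irrev <- !vapply(problem$network$reactions, `[[`, TRUE, "reversible")
  p <- numeric(length(info$lower))
  for (scale in c(40, 20, 10, 5, 2, 0)) {
    ok <- FALSE
    for (try in 1:20) {
      t <- anchor + stats::runif(d, -scale, scale)
      t <- pmin(pmax(t, info$lower[seq_len(d)]), info$upper[seq_len(d)])
      v <- flux_from_free(problem$basis, stats::setNames(t, problem$basis$free_ids))
      if (all(v[irrev] >= -1e-9)) { p[seq_len(d)] <- t; ok <- TRUE; break }
    }
    if (ok) break
  }
  if (!ok) p[seq_len(d)] <- anchor
  p[d + seq_len(info$n_exch)] <- stats::runif(info$n_exch, 0, 0.6)
  p
}

#' Fit fluxes by multi-start weighted least squares
#'
#' Runs bounded Levenberg-Marquardt minimization of the weighted
#' residuals from `restarts` random initial points (plus an optional
#' user-supplied start) and returns the best converged solution.
#' Deterministic given `settings$seed`.
#'
#' @param problem an `mfa_problem`.
#' @param start optional initial parameter vector.
#' @return an `mfa_fit`: best `flux_vector`, `ssr`, `params`,
#'   `residuals`, `dof`, a per-restart convergence table, and the seed.
#' @export
fit_fluxes <- function(problem, start = NULL) {
  info <- problem_par_info(problem)
  set.seed(problem$settings$seed)
  anchor <- feasible_anchor(problem)
  starts <- list()
  if (!is.null(start)) starts[[length(starts) + 1L]] <- start
  for (i in seq_len(problem$settings$restarts))
    starts[[length(starts) + 1L]] <- random_start(problem, info, anchor)
  best <- NULL
  tab <- data.frame(restart = integer(0), ssr = numeric(0), converged = logical(0))
  for (i in seq_along(starts)) {
    fitres <- tryCatch(
      minpack.lm::nls.lm(par = starts[[i]],
                         lower = info$lower, upper = info$upper,
                         fn = function(p) problem_residuals(problem, p),
                         control = minpack.lm::nls.lm.control(
                           maxiter = problem$settings$maxiter,
                           ftol = 1e-10, ptol = 1e-10)),
      error = function(e) NULL)
    if (is.null(fitres)) {
      tab <- rbind(tab, data.frame(restart = i, ssr = NA, converged = FALSE))
      next
    }
    ssr <- sum(fitres$fvec^2)
    tab <- rbind(tab, data.frame(restart = i, ssr = ssr,
                                 converged = fitres$info %in% 1:4))
    if (is.null(best) || ssr < best$ssr)
      best <- list(params = fitres$par, ssr = ssr, nls = fitres)
  }
  if (is.null(best)) stop("no-convergence: all restarts failed", call. = FALSE)
  fl <- params_to_fluxes(problem, best$params)
  res <- problem_residuals(problem, best$params)
  per_exp <- vapply(seq_along(problem$experiments), function(e)
    sum(res[startsWith(names(res), paste0("ex", e, "_"))]^2), numeric(1))
  structure(list(fluxes = fl, ssr = best$ssr, params = stats::setNames(best$params, info$names),
                 residuals = res, ssr_per_experiment = per_exp,
                 dof = problem_dof(problem),
                 restart_table = tab, seed = problem$settings$seed,
                 problem = problem),
            class = "mfa_fit")
}

#' @export
print.mfa_fit <- function(x, ...) {
  cat(sprintf("mfa_fit: SSR = %.4g on %d dof (%d restarts, seed %d)\n",
              x$ssr, x$dof, nrow(x$restart_table), x$seed))
  cat("  free fluxes:\n")
  d <- x$problem$basis$dim
  for (id in x$problem$basis$free_ids)
    cat(sprintf("    %-10s %8.3f\n", id, x$fluxes$net[[id]]))
  invisible(x)
}

#' Linearized standard errors of the net fluxes
#'
#' Propagates the parameter covariance `(J'J)^-1` at the optimum through
#' the affine free-flux map.  Exchange parameters contribute nothing to
#' net fluxes.
#'
#' @param fit an `mfa_fit`.
#' @return named vector of net-flux standard errors; unidentifiable
#'   directions surface as very large values.
#' @export
flux_se <- function(fit) {
  problem <- fit$problem
  J <- numerical_jacobian(function(p) problem_residuals(problem, p), fit$params)
  H <- crossprod(J)
  # flat (non-identifiable) directions get a huge, not zero, variance
  eig <- eigen(H, symmetric = TRUE)
  lmax <- max(eig$values, 1e-12)
  inv <- ifelse(eig$values > 1e-10 * lmax, 1 / pmax(eig$values, 1e-300), 1e12)
  covp <- eig$vectors %*% (inv * t(eig$vectors))
  d <- problem$basis$dim
  D <- cbind(problem$basis$M, matrix(0, nrow(problem$basis$M),
                                     length(problem$exchange_ids)))
  se <- sqrt(pmax(diag(D %*% covp %*% t(D)), 0))
  stats::setNames(se, rownames(problem$basis$M))
}

numerical_jacobian <- function(f, x, eps = 1e-6) {
  f0 <- f(x)
  J <- matrix(0, length(f0), length(x))
  for (j in seq_along(x)) {
    xj <- x; xj[j] <- xj[j] + eps
    J[, j] <- (f(xj) - f0) / eps
  }
  J
}

#' Monte-Carlo confidence intervals for the fitted fluxes
#'
#' Parametric bootstrap: every measured MID entry and rate is perturbed by
#' Gaussian noise of its own standard deviation (MIDs clipped at zero and
#' renormalized), the fluxes are refitted starting from the point
#' estimate, and per-reaction 2.5/97.5 percentiles of the refitted net
#' fluxes form the 95% intervals.  Deterministic given `seed`.
#'
#' @param problem an `mfa_problem`.
#' @param fit an `mfa_fit` for `problem`.
#' @param n_samples number of Monte-Carlo replicates.
#' @param seed RNG seed.
#' @param maxiter LM iteration cap per refit.
#' @return an `mfa_ci`: data frame (reaction, lower, upper, estimate)
#'   plus `n_samples`, `seed`, `n_failed`.
#' @export
monte_carlo_ci <- function(problem, fit,
                           n_samples = problem$settings$n_monte_carlo,
                           seed = problem$settings$seed, maxiter = 30L) {
  set.seed(seed)
  info <- problem_par_info(problem)
  draws <- matrix(NA_real_, n_samples, length(fit$fluxes$net),
                  dimnames = list(NULL, names(fit$fluxes$net)))
  n_failed <- 0L
  for (s in seq_len(n_samples)) {
    pp <- problem
    for (e in seq_along(pp$experiments)) {
      for (fid in names(pp$experiments[[e]]$mids)) {
        m <- pp$experiments[[e]]$mids[[fid]]
        sd <- pmax(m$sd, SIGMA_FLOOR)
        v <- pmax(m$mid + stats::rnorm(length(m$mid), 0, sd), 0)
        pp$experiments[[e]]$mids[[fid]]$mid <- v / sum(v)
      }
    }
    if (!is.null(pp$rates) && nrow(pp$rates))
      pp$rates$value <- pp$rates$value + stats::rnorm(nrow(pp$rates), 0, pp$rates$sd)
    refit <- tryCatch(
      minpack.lm::nls.lm(par = fit$params, lower = info$lower, upper = info$upper,
                         fn = function(p) problem_residuals(pp, p),
                         control = minpack.lm::nls.lm.control(maxiter = maxiter,
                                                              ftol = 1e-10, ptol = 1e-10)),
      error = function(e) NULL)
    if (is.null(refit)) { n_failed <- n_failed + 1L; next }
    draws[s, ] <- params_to_fluxes(pp, refit$par)$net
  }
  if (n_failed > 0.2 * n_samples)
    stop(sprintf("excessive refit failures in Monte-Carlo CI: %d of %d",
                 n_failed, n_samples), call. = FALSE)
  ok <- stats::complete.cases(draws)
  qs <- apply(draws[ok, , drop = FALSE], 2, stats::quantile,
              probs = c(0.025, 0.975), names = FALSE)
  out <- data.frame(reaction = colnames(draws), lower = qs[1, ], upper = qs[2, ],
                    estimate = fit$fluxes$net[colnames(draws)],
                    row.names = NULL, stringsAsFactors = FALSE)
  structure(list(intervals = out, n_samples = n_samples, seed = seed,
                 n_failed = n_failed, draws = draws),
            class = "mfa_ci")
}

#' @export
print.mfa_ci <- function(x, ...) {
  cat(sprintf("mfa_ci: 95%% Monte-Carlo intervals from %d samples (seed %d, %d failed)\n",
              x$n_samples, x$seed, x$n_failed))
  invisible(x)
}

#' Normalize a flux vector to glucose uptake = 100
#'
#' @param fluxes a `flux_vector` (or an `mfa_fit`, whose fluxes are used).
#' @param network the network providing the uptake reaction id.
#' @return a `flux_vector` rescaled so the uptake reaction carries 100.
#' @export
normalize_to_uptake <- function(fluxes, network) {
  if (inherits(fluxes, "mfa_fit")) fluxes <- fluxes$fluxes
  u <- fluxes$net[[network$uptake_reaction]]
  if (!is.finite(u) || u <= 0) stop("zero or negative uptake flux", call. = FALSE)
  flux_vector(fluxes$net * (100 / u), fluxes$exchange * (100 / u))
}
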