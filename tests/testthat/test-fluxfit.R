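test_that("free-flux basis dimensions match the network topology", {
  chain <- load_network(write_model(c(
    "u,A (ab) = B (ab),0,measured,",
    "r,B (ab) = C (ab),0,free,",
    "o,C (ab) = Cx (ab),0,free,")))
  b <- free_flux_basis(chain, c(u = 100))
  expect_equal(b$dim, 0L)
  expect_equal(unname(b$v0[c("u", "r", "o")]), c(100, 100, 100))

  branch <- toy_split_net()
  b2 <- free_flux_basis(branch, c(tupt = 100))
  expect_equal(b2$dim, 1L)
  v <- flux_from_free(b2, setNames(30, b2$free_ids))
  S <- stoichiometric_matrix(branch)
  expect_lt(max(abs(S %*% v)), 1e-9)
})

test_that("shipped-model basis dimension matches an elimination oracle", {
  scen <- osmoflux_scenario(0)
  b <- free_flux_basis(scen$network, scen$fixed)
  S <- stoichiometric_matrix(scen$network)
  E <- matrix(0, length(scen$fixed), ncol(S),
              dimnames = list(names(scen$fixed), colnames(S)))
  E[cbind(seq_along(scen$fixed), match(names(scen$fixed), colnames(S)))] <- 1
  A <- rbind(S, E)
  expect_equal(b$dim, ncol(A) - qr(A)$rank)
  # every mapped point satisfies the constraints
  set.seed(5)
  t <- setNames(runif(b$dim, 5, 40), b$free_ids)
  v <- flux_from_free(b, t)
  expect_lt(max(abs(S %*% v)), 1e-8)
  expect_equal(unname(v[names(scen$fixed)]), unname(scen$fixed), tolerance = 1e-8)
})

test_that("infeasible fixed rates are reported with the violated constraint", {
  chain <- load_network(write_model(c(
    "u,A (ab) = B (ab),0,measured,",
    "r,B (ab) = C (ab),0,free,",
    "o,C (ab) = Cx (ab),0,free,")))
  expect_error(free_flux_basis(chain, c(u = 100, r = 50)), "infeasible fixed rates")
})

make_toy_problem <- function(true_free = 60, sd = 0.01, seed = 1, noise = TRUE,
                             restarts = 2, rates = NULL) {
  net <- toy_split_net()
  frags <- toy_fragments(c("P", "Q"), c(1, 1))
  tracer <- tracer_mixture(c("10", "00"), c(1, 0))
  fixed <- c(tupt = 100)
  basis <- free_flux_basis(net, fixed)
  truth <- flux_vector(flux_from_free(basis, setNames(true_free, basis$free_ids)))
  emu <- emu_decompose(net, fragment_targets(frags))
  sk <- simulate_fragment_mids(net, emu, truth, tracer, frags)
  set.seed(seed)
  mids <- lapply(sk, function(m) {
    v <- if (noise) pmax(m + rnorm(length(m), 0, sd), 0) else m
    list(mid = v / sum(v), sd = rep(sd, length(m)))
  })
  prob <- mfa_problem(net, frags, list(list(tracer = tracer, mids = mids)),
                      rates, fixed, settings = list(restarts = restarts,
                                                    seed = seed, maxiter = 40))
  list(problem = prob, truth = truth, net = net)
}

test_that("objective is an exactly weighted sum of squares", {
  tp <- make_toy_problem(noise = FALSE)
  p_truth <- tp$truth$net[tp$problem$basis$free_ids]
  expect_lt(objective(tp$problem, p_truth), 1e-16)

  # one residual of 2 sigma -> SSR 4
  tp2 <- make_toy_problem(noise = FALSE)
  m <- tp2$problem$experiments[[1]]$mids$P_f
  m$mid <- m$mid + c(-0.02, 0.02)  # 2 sigma at sd = 0.01 on both entries
  tp2$problem$experiments[[1]]$mids$P_f <- m
  expect_equal(objective(tp2$problem, p_truth), 8, tolerance = 1e-8)

  # random perturbation: direct summation oracle
  set.seed(9)
  tp3 <- make_toy_problem(noise = FALSE)
  eps <- list(P_f = rnorm(2, 0, 0.01), Q_f = rnorm(2, 0, 0.01))
  hand <- 0
  for (f in names(eps)) {
    mm <- tp3$problem$experiments[[1]]$mids[[f]]
    mm$mid <- mm$mid + eps[[f]]
    tp3$problem$experiments[[1]]$mids[[f]] <- mm
    hand <- hand + sum((eps[[f]] / 0.01)^2)
  }
  expect_equal(objective(tp3$problem, p_truth), hand, tolerance = 1e-6)
})

test_that("noise-free synthetic data is recovered essentially exactly", {
  tp <- make_toy_problem(noise = FALSE, restarts = 3)
  fit <- fit_fluxes(tp$problem)
  expect_lt(fit$ssr, 1e-6)
  expect_equal(fit$fluxes$net[["p1"]], tp$truth$net[["p1"]], tolerance = 1e-3)
  S <- stoichiometric_matrix(tp$net)
  expect_lt(max(abs(S %*% fit$fluxes$net)), 1e-8)
})

test_that("fits are deterministic given the seed", {
  tp1 <- make_toy_problem(seed = 7)
  tp2 <- make_toy_problem(seed = 7)
  f1 <- fit_fluxes(tp1$problem)
  f2 <- fit_fluxes(tp2$problem)
  expect_identical(f1$fluxes$net, f2$fluxes$net)
  expect_identical(f1$ssr, f2$ssr)
  c1 <- monte_carlo_ci(tp1$problem, f1, n_samples = 25, seed = 3)
  c2 <- monte_carlo_ci(tp2$problem, f2, n_samples = 25, seed = 3)
  expect_identical(c1$intervals, c2$intervals)
})

test_that("estimation error shrinks as measurement noise goes to zero", {
  errs <- vapply(c(0.02, 0.005, 0.00125), function(s) {
    tp <- make_toy_problem(sd = s, seed = 21)
    fit <- fit_fluxes(tp$problem)
    abs(fit$fluxes$net[["p1"]] - tp$truth$net[["p1"]])
  }, numeric(1))
  expect_true(all(diff(errs) < 0))
})

test_that("rates-only problems expose non-identifiable labeling directions", {
  rates <- data.frame(reaction = c("sp", "sq"), value = c(100, 100), sd = c(3, 3))
  tp <- make_toy_problem(rates = rates)
  # remove the labeling information entirely
  tp$problem$experiments[[1]]$mids <- list()
  fit <- fit_fluxes(tp$problem)
  se <- flux_se(fit)
  # the positional split p1 vs p2 cannot be resolved by rates alone
  expect_gt(se[["p1"]], 1e3)
})

test_that("Monte-Carlo CIs behave at the degenerate limits", {
  tp <- make_toy_problem(sd = 0.01, seed = 2)
  fit <- fit_fluxes(tp$problem)

  ci1 <- monte_carlo_ci(tp$problem, fit, n_samples = 1, seed = 5)
  expect_equal(ci1$intervals$lower, ci1$intervals$upper, tolerance = 1e-12)

  tiny <- tp$problem
  for (f in names(tiny$experiments[[1]]$mids))
    tiny$experiments[[1]]$mids[[f]]$sd <- rep(1e-6, 2)
  fit2 <- fit_fluxes(tiny)
  ci2 <- monte_carlo_ci(tiny, fit2, n_samples = 30, seed = 5)
  width <- ci2$intervals$upper - ci2$intervals$lower
  # sigma floor keeps weights finite; widths collapse towards zero
  expect_lt(max(width[ci2$intervals$reaction == "p1"]), 2)
})

test_that("normalization rescales the uptake reaction to 100", {
  net <- toy_split_net()
  v <- setNames(c(5, 3, 2, 2.5, 2.5), names(net$reactions))
  fl <- flux_vector(v)
  out <- normalize_to_uptake(fl, net)
  expect_equal(out$net[["tupt"]], 100)
  expect_equal(out$net[["p1"]], 60)
  again <- normalize_to_uptake(out, net)
  expect_equal(again$net, out$net)
  expect_error(normalize_to_uptake(flux_vector(v * 0), net), "zero or negative uptake")
})
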