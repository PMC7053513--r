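test_that("EMU decomposition traces minimal precursor sets", {
  net <- load_network(write_model(c(
    "u,A (ab) = B (ab),0,measured,",
    "o,B (ab) = Bx (ab),0,free,")))
  emu <- emu_decompose(net, list(list(met = "B", indices = c(1, 2))))
  expect_setequal(names(emu$nodes), c("B:1.2", "A:1.2"))

  net2 <- load_network(write_model(c(
    "u,A (abc) = B (ab) + C (c),0,measured,",
    "ob,B (ab) = Bx (ab),0,free,",
    "oc,C (a) = Cx (a),0,free,")))
  emu2 <- emu_decompose(net2, list(list(met = "B", indices = c(1, 2))))
  expect_setequal(names(emu2$nodes), c("B:1.2", "A:1.2"))  # C never instantiated
})

test_that("unreachable targets raise an error", {
  net <- load_network(write_model(c(
    "u,A (ab) = B (ab),0,measured,",
    "o,B (ab) = Bx (ab),0,free,")))
  expect_error(emu_decompose(net, list(list(met = "B", indices = 3))),
               "invalid carbon subset")
})

test_that("unlabeled and fully labeled tracers give degenerate MIDs", {
  for (net in list(toy_cleavage_net(), toy_cycle_net())) {
    nsub <- n_carbons(net, net$substrate)
    basis <- free_flux_basis(net, setNames(100, net$uptake_reaction))
    fl <- flux_vector(flux_from_free(basis, setNames(rep(30, basis$dim), basis$free_ids)))
    mets <- net$metabolites
    targets <- lapply(mets$id[mets$role == "balanced"], function(m)
      list(met = m, indices = seq_len(n_carbons(net, m))))
    emu <- emu_decompose(net, targets)
    un <- simulate_mids(net, emu, fl, tracer_mixture(strrep("0", nsub), 1))
    for (m in un) expect_equal(m, c(1, numeric(length(m) - 1)), tolerance = 1e-12)
    full <- simulate_mids(net, emu, fl, tracer_mixture(strrep("1", nsub), 1))
    for (m in full) expect_equal(m, c(numeric(length(m) - 1), 1), tolerance = 1e-12)
  }
})

test_that("EMU cascade matches brute-force isotopomer enumeration on toys", {
  set.seed(7)
  cases <- list(
    list(net = toy_cleavage_net(), tracer = tracer_mixture(c("100", "010", "000"),
                                                           c(0.5, 0.2, 0.3))),
    list(net = toy_cycle_net(), tracer = tracer_mixture(c("10", "11", "00"),
                                                        c(0.4, 0.3, 0.3))),
    list(net = toy_exchange_net(), tracer = tracer_mixture(c("10", "00"), c(0.5, 0.5))))
  for (case in cases) {
    net <- case$net
    basis <- free_flux_basis(net, setNames(100, net$uptake_reaction))
    for (rep in 1:3) {
      free <- setNames(runif(basis$dim, 10, 90), basis$free_ids)
      v <- flux_from_free(basis, free)
      irrev <- !vapply(net$reactions, `[[`, TRUE, "reversible")
      if (any(v[irrev] < 0)) next
      rev_ids <- names(net$reactions)[!irrev]
      fl <- flux_vector(v, setNames(runif(length(rev_ids), 0, 50), rev_ids))
      mets <- net$metabolites
      bal <- mets$id[mets$role == "balanced"]
      targets <- lapply(bal, function(m) list(met = m, indices = seq_len(n_carbons(net, m))))
      emu <- emu_decompose(net, targets)
      sim <- simulate_mids(net, emu, fl, case$tracer)
      iso <- oracle_isotopomers(net, fl, case$tracer)
      for (m in bal) {
        idx <- seq_len(n_carbons(net, m))
        expect_lt(max(abs(sim[[emu_key(m, idx)]] - oracle_mid(iso[[m]], idx))), 1e-10)
      }
    }
  }
})

test_that("EMU MIDs of partial carbon subsets also match the oracle", {
  net <- toy_cleavage_net()
  basis <- free_flux_basis(net, setNames(100, net$uptake_reaction))
  fl <- flux_vector(flux_from_free(basis, setNames(60, basis$free_ids)),
                    c(r2 = 20))
  tracer <- tracer_mixture(c("110", "001", "000"), c(0.3, 0.3, 0.4))
  targets <- list(list(met = "E", indices = c(1, 3)),
                  list(met = "C", indices = 2),
                  list(met = "B", indices = c(2, 3)))
  emu <- emu_decompose(net, targets)
  sim <- simulate_mids(net, emu, fl, tracer)
  iso <- oracle_isotopomers(net, fl, tracer)
  expect_lt(max(abs(sim[["E:1.3"]] - oracle_mid(iso[["E"]], c(1, 3)))), 1e-10)
  expect_lt(max(abs(sim[["C:2"]] - oracle_mid(iso[["C"]], 2))), 1e-10)
  expect_lt(max(abs(sim[["B:2.3"]] - oracle_mid(iso[["B"]], c(2, 3)))), 1e-10)
})

test_that("MID convolution equals polynomial multiplication", {
  expect_equal(convolve_mid(c(1, 0), c(1, 0)), c(1, 0, 0))
  expect_equal(convolve_mid(c(0.5, 0.5), c(0.5, 0.5)), c(0.25, 0.5, 0.25))
  set.seed(1)
  for (i in 1:5) {
    a <- rsimplex(4); b <- rsimplex(3)
    # independent oracle: coefficients of the product polynomial
    pa <- function(x) sum(a * x^(0:3)); pb <- function(x) sum(b * x^(0:2))
    xs <- seq(0.1, 1.2, length.out = 6)
    V <- outer(xs, 0:5, `^`)
    coef <- solve(V, vapply(xs, pa, 0) * vapply(xs, pb, 0))
    expect_equal(convolve_mid(a, b), coef, tolerance = 1e-9)
    expect_equal(sum(convolve_mid(a, b)), 1, tolerance = 1e-12)
  }
})

test_that("flux-scale invariance: scaling all fluxes leaves MIDs unchanged", {
  scen <- osmoflux_scenario(0)
  net <- scen$network
  emu <- emu_decompose(net, fragment_targets(scen$fragments))
  m1 <- simulate_fragment_mids(net, emu, scen$truth, scen$tracers$c1, scen$fragments)
  scaled <- flux_vector(scen$truth$net * 3.7, scen$truth$exchange * 3.7)
  m2 <- simulate_fragment_mids(net, emu, scaled, scen$tracers$c1, scen$fragments)
  expect_equal(m1, m2, tolerance = 1e-12)
})

test_that("simplex is preserved through the whole cascade on the shipped model", {
  scen <- osmoflux_scenario(1.2)
  emu <- emu_decompose(scen$network, fragment_targets(scen$fragments))
  mids <- simulate_mids(scen$network, emu, scen$truth, scen$tracers$u50)
  sums <- vapply(mids, sum, numeric(1))
  expect_lt(max(abs(sums - 1)), 1e-9)
  expect_true(all(vapply(mids, min, numeric(1)) > -1e-12))
})

test_that("infinite-exchange limit equilibrates substrate and product pools", {
  net <- toy_exchange_net()
  basis <- free_flux_basis(net, setNames(100, net$uptake_reaction))
  tracer <- tracer_mixture(c("10", "00"), c(0.7, 0.3))
  targets <- list(list(met = "B", indices = 1:2), list(met = "C", indices = 1:2))
  emu <- emu_decompose(net, targets)
  for (ex in c(1e3, 1e5)) {
    fl <- flux_vector(flux_from_free(basis, numeric(0)), c(ex = ex))
    sim <- simulate_mids(net, emu, fl, tracer)
    expect_lt(max(abs(sim[["B:1.2"]] - sim[["C:1.2"]])), 10 / ex)
  }
})

test_that("isotopic steady-state check flags drifting labeling", {
  scen <- osmoflux_scenario(0)
  emu <- emu_decompose(scen$network, fragment_targets(scen$fragments))
  sk <- simulate_fragment_mids(scen$network, emu, scen$truth, scen$tracers$c1,
                               scen$fragments)
  expect_true(check_isotopic_steady_state(list(sk, sk, sk))$is_steady)
  expect_equal(check_isotopic_steady_state(list(sk, sk))$max_deviation, 0)

  drift <- sk
  d <- drift[["ALA_M-57"]]; d[1] <- d[1] + 0.05; drift[["ALA_M-57"]] <- d / sum(d)
  res <- check_isotopic_steady_state(list(sk, drift), tol = 0.01)
  expect_false(res$is_steady)
  expect_equal(res$worst_fragment, "ALA_M-57")

  # three sampling points with GC-MS-scale noise stay within tolerance
  set.seed(11)
  noisy <- lapply(1:3, function(i)
    lapply(sk, function(m) { v <- pmax(m + rnorm(length(m), 0, 0.002), 0); v / sum(v) }))
  names(noisy[[1]]) <- names(noisy[[2]]) <- names(noisy[[3]]) <- names(sk)
  expect_true(check_isotopic_steady_state(noisy, tol = 0.01)$is_steady)

  expect_error(check_isotopic_steady_state(list(sk, sk[-1])), "fragment-set mismatch")
})
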