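test_that("a minimal two-reaction model loads with correct roles", {
  net <- load_network(write_model(c(
    "uptk,GLC (abcdef) = G6P (abcdef),0,measured,",
    "sink,G6P (abcdef) = X,0,free,")))
  expect_s3_class(net, "mfa_network")
  expect_length(net$reactions, 2)
  roles <- setNames(net$metabolites$role, net$metabolites$id)
  expect_equal(roles[["GLC"]], "substrate")
  expect_equal(roles[["G6P"]], "balanced")
  expect_equal(net$substrate, "GLC")
  expect_equal(net$uptake_reaction, "uptk")
})

test_that("carbon imbalance is rejected with the reaction named", {
  expect_error(load_network(write_model(c(
    "ok,A (ab) = B (ab),0,free,",
    "bad,B (ab) = C (abc),0,free,",
    "out,C (abc) = Cx (abc),0,free,"))),
    "carbon-imbalance.*'bad'")
  expect_error(load_network(write_model(c(
    "lost,A (abc) = B (ab),0,free,",
    "out,B (ab) = Bx (ab),0,free,"))),
    "carbon-imbalance.*'lost'")
})

test_that("inconsistent carbon counts raise an unknown-metabolite error", {
  expect_error(load_network(write_model(c(
    "r1,A (ab) = B (ab),0,free,",
    "r2,B (abc) = C (abc),0,free,"))),
    "inconsistent carbon count")
})

test_that("the shipped model loads with every reaction carbon-balanced", {
  net <- bmeg_network()
  # exhaustive per-reaction letter-multiset check, independent of loader
  for (rxn in net$reactions) {
    for (v in rxn$variants) {
      sub <- sort(unlist(lapply(v$substrates, `[[`, "atoms")))
      prod <- sort(unlist(lapply(v$products, `[[`, "atoms")))
      has_sink <- any(vapply(v$products, function(s) is.null(s$atoms), logical(1)))
      if (has_sink) {
        expect_true(all(prod %in% sub), label = paste("letters of", rxn$id))
      } else {
        expect_identical(sub, prod, label = paste("letters of", rxn$id))
      }
    }
  }
  # all pathway blocks present
  expect_true(all(c("pgi", "pfk", "zwf", "gnd", "tkt1", "tal", "tkt2",
                    "cs", "icd", "akgdh", "sdh", "fum", "mdh",
                    "pepc", "pyc", "pox",
                    "proj", "proa", "proh", "phaa", "phab", "phac")
                  %in% names(net$reactions)))
})

test_that("stoichiometric matrix has signed per-occurrence coefficients", {
  net <- load_network(write_model(c(
    "r0,A (ab) = B (ab),0,measured,",
    "dim,B (ab) + B (cd) = D (abcd),0,free,",
    "out,D (abcd) = Dx (abcd),0,free,")))
  S <- stoichiometric_matrix(net)
  expect_equal(S["B", "dim"], -2)
  expect_equal(S["D", "dim"], 1)
  expect_equal(S["B", "r0"], 1)
})

test_that("matrix construction is deterministic and rank is as expected", {
  S1 <- stoichiometric_matrix(bmeg_network())
  S2 <- stoichiometric_matrix(bmeg_network())
  expect_identical(S1, S2)
  # independent elimination oracle for the rank
  rank_elim <- function(M, tol = 1e-9) {
    M <- unname(M); r <- 0
    for (j in seq_len(ncol(M))) {
      if (r == nrow(M)) break
      p <- which.max(abs(M[(r + 1):nrow(M), j])) + r
      if (abs(M[p, j]) < tol) next
      M[c(r + 1, p), ] <- M[c(p, r + 1), ]
      r <- r + 1
      for (i in seq_len(nrow(M))[-(r)])
        M[i, ] <- M[i, ] - M[i, j] / M[r, j] * M[r, ]
    }
    r
  }
  expect_equal(qr(S1)$rank, rank_elim(S1))
})

test_that("cofactor CO2 counts are cross-checked against atom maps", {
  expect_warning(load_network(write_model(c(
    "r,A (ab) = B (a) + CO2 (b),0,free,",
    "o,B (a) = Bx (a),0,free,"))),
    "cofactor CO2 count")
})

test_that("biomass interpolation is exact at anchors and linear between", {
  bio <- load_biomass()
  at0 <- interpolate_biomass(bio, 0)
  ref0 <- bio[bio$condition == 0, ]
  expect_equal(at0$demand_mmol_per_gCDW[match(ref0$precursor, at0$precursor)],
               ref0$demand_mmol_per_gCDW)
  at09 <- interpolate_biomass(bio, 0.9)
  ref06 <- bio[bio$condition == 0.6, ]
  ref12 <- bio[bio$condition == 1.2, ]
  for (p in at09$precursor) {
    expect_equal(at09$demand_mmol_per_gCDW[at09$precursor == p],
                 mean(c(ref06$demand_mmol_per_gCDW[ref06$precursor == p],
                        ref12$demand_mmol_per_gCDW[ref12$precursor == p])),
                 tolerance = 1e-12)
  }
  expect_warning(out <- interpolate_biomass(bio, 1.8), "extrapolation")
  expect_equal(out$demand_mmol_per_gCDW,
               interpolate_biomass(bio, 1.2)$demand_mmol_per_gCDW)
})

test_that("midpoint interpolation of two anchors halves the difference", {
  comp <- structure(data.frame(condition = c(0, 1.2), precursor = "ALA",
                               demand_mmol_per_gCDW = c(1, 2)),
                    class = c("biomass_composition", "data.frame"))
  expect_equal(interpolate_biomass(comp, 0.6)$demand_mmol_per_gCDW, 1.5)
  expect_error(interpolate_biomass(comp[0, ], 0.5), "empty anchor")
})
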