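# Steady-state labeling simulation: solve the EMU cascade size by size as
# linear systems to obtain carbon-skeleton mass isotopomer distributions.

#' Define a glucose tracer mixture
#'
#' @param patterns character vector of positional label patterns, one
#'   character per carbon (`"100000"` = 1-13C glucose).
#' @param fractions molar fractions, summing to 1.
#' @return a `tracer_mixture`.
#' @export
tracer_mixture <- function(patterns, fractions) {
  stopifnot(length(patterns) == length(fractions), all(fractions >= 0))
  if (abs(sum(fractions) - 1) > 1e-9) stop("tracer fractions must sum to 1", call. = FALSE)
  nc <- unique(nchar(patterns))
  if (length(nc) != 1L) stop("tracer patterns must have equal length", call. = FALSE)
  structure(list(patterns = patterns, fractions = fractions, n_carbons = nc),
            class = "tracer_mixture")
}

#' 1-13C glucose tracer at a given positional purity
#'
#' Models 99% 1-13C glucose as a two-component mixture: `purity` labeled
#' at C1, the remainder unlabeled.
#' @param purity fraction labeled at C1.
#' @return a `tracer_mixture`.
#' @export
tracer_1c13 <- function(purity = 0.99) {
  tracer_mixture(c("100000", "000000"), c(purity, 1 - purity))
}

#' 50% U-12C / 50% U-13C glucose tracer
#' @param frac_u13 fraction of uniformly labeled glucose.
#' @return a `tracer_mixture`.
#' @export
tracer_u13c50 <- function(frac_u13 = 0.5) {
  tracer_mixture(c("111111", "000000"), c(frac_u13, 1 - frac_u13))
}

#' MID of a substrate EMU under a tracer mixture
#' @param tracer a `tracer_mixture`.
#' @param idx carbon indices of the EMU.
#' @return MID vector of length `length(idx) + 1`.
#' @export
tracer_emu_mid <- function(tracer, idx) {
  out <- numeric(length(idx) + 1L)
  for (i in seq_along(tracer$patterns)) {
    bits <- as.integer(strsplit(tracer$patterns[i], "")[[1]])
    shift <- sum(bits[idx])
    out[shift + 1L] <- out[shift + 1L] + tracer$fractions[i]
  }
  out
}

#' Directed (forward/backward) fluxes of every reaction
#'
#' Reversible reactions carry a bidirectional exchange component on top of
#' the net flux: `v_fwd = max(net,0) + exch`, `v_bwd = max(-net,0) + exch`.
#'
#' @param network an `mfa_network`.
#' @param fluxes a `flux_vector` (see [flux_vector()]).
#' @return list with named vectors `fwd` and `bwd`.
#' @export
directed_fluxes <- function(network, fluxes) {
  ids <- names(network$reactions)
  net <- fluxes$net[ids]
  exch <- stats::setNames(numeric(length(ids)), ids)
  if (length(fluxes$exchange)) exch[names(fluxes$exchange)] <- fluxes$exchange
  rev <- vapply(network$reactions, `[[`, TRUE, "reversible")
  fwd <- ifelse(rev, pmax(net, 0) + exch, net)
  bwd <- ifelse(rev, pmax(-net, 0) + exch, 0)
  list(fwd = stats::setNames(fwd, ids), bwd = stats::setNames(bwd, ids))
}

#' Construct a flux vector
#'
#' @param net named numeric vector of net fluxes (one per reaction, in %
#'   of glucose uptake).
#' @param exchange named numeric vector of exchange fluxes for (a subset
#'   of) the reversible reactions; missing entries are 0.
#' @return a `flux_vector`.
#' @export
flux_vector <- function(net, exchange = numeric(0)) {
  structure(list(net = net, exchange = exchange), class = "flux_vector")
}

#' Simulate steady-state mass isotopomer distributions
#'
#' Solves the EMU cascade for the given flux vector and tracer, returning
#' the carbon-skeleton MID (no natural-isotope effects) of every EMU
#' requested at decomposition time.
#'
#' @param network an `mfa_network`.
#' @param emu an `emu_network` from [emu_decompose()].
#' @param fluxes a `flux_vector`; must satisfy the stoichiometric balance.
#' @param tracer a `tracer_mixture` for the substrate.
#' @return named list of MID vectors for all non-input EMUs; target EMU
#'   keys in `attr(,"targets")`.
#' @export
simulate_mids <- function(network, emu, fluxes, tracer) {
  dv <- directed_fluxes(network, fluxes)
  solved <- new.env(parent = emptyenv())

  input_mid <- function(node) {
    if (node$met == network$substrate) tracer_emu_mid(tracer, node$idx)
    else c(1, numeric(length(node$idx)))  # gas species enter unlabeled
  }
  get_mid <- function(key) {
    if (!is.null(solved[[key]])) return(solved[[key]])
    node <- emu$nodes[[key]]
    if (isTRUE(node$input)) {
      m <- input_mid(node); assign(key, m, envir = solved); return(m)
    }
    stop(sprintf("internal: EMU %s requested before being solved", key))
  }

  for (k in emu$sizes) {
    keys <- emu$by_size[[as.character(k)]]
    if (!length(keys)) next
    n <- length(keys)
    idx_of <- stats::setNames(seq_len(n), keys)
    A <- matrix(0, n, n, dimnames = list(keys, keys))
    B <- matrix(0, n, k + 1L)
    for (key in keys) {
      i <- idx_of[[key]]
      node <- emu$nodes[[key]]
      for (term in node$terms) {
        v <- if (term$dir == "f") dv$fwd[[term$rxn]] else dv$bwd[[term$rxn]]
        f <- term$w * v
        if (f == 0) next
        A[i, i] <- A[i, i] + f
        src_keys <- vapply(term$sources, function(s) emu_key(s$met, s$idx), "")
        if (length(src_keys) == 1L && !isTRUE(emu$nodes[[src_keys]]$input) &&
            emu$nodes[[src_keys]]$size == k) {
          A[i, src_keys] <- A[i, src_keys] - f
        } else {
          m <- 1
          for (sk in src_keys) m <- convolve_mid(m, get_mid(sk))
          B[i, ] <- B[i, ] + f * m
        }
      }
      if (A[i, i] <= 0)
        stop(sprintf("singular EMU system: no flux produces %s", key), call. = FALSE)
    }
    X <- tryCatch(solve(A, B), error = function(e)
      stop(sprintf("singular EMU system at size %d: %s", k, conditionMessage(e)),
           call. = FALSE))
    for (key in keys) assign(key, X[idx_of[[key]], ], envir = solved)
  }

  out <- as.list(solved)
  out <- out[!vapply(emu$nodes[names(out)], function(n) isTRUE(n$input), logical(1))]
  attr(out, "targets") <- emu$targets
  out
}

#' Simulate the MIDs of a measured fragment panel
#'
#' Convenience wrapper mapping fragment rows (amino acid + backbone
#' indices) to their EMU MIDs.
#'
#' @inheritParams simulate_mids
#' @param fragments fragment table from [load_fragment_table()].
#' @return named list of skeleton MIDs keyed by `fragment_id`.
#' @export
simulate_fragment_mids <- function(network, emu, fluxes, tracer, fragments) {
  mids <- simulate_mids(network, emu, fluxes, tracer)
  out <- lapply(seq_len(nrow(fragments)), function(i) {
    key <- emu_key(fragments$amino_acid[i], fragments$backbone[[i]])
    m <- mids[[key]]
    if (is.null(m)) stop(sprintf("fragment EMU %s not in decomposition", key), call. = FALSE)
    m
  })
  stats::setNames(out, fragments$fragment_id)
}

#' Fragment panel EMU targets
#' @param fragments fragment table.
#' @return list of targets for [emu_decompose()].
#' @export
fragment_targets <- function(fragments) {
  lapply(seq_len(nrow(fragments)), function(i)
    list(met = fragments$amino_acid[i], indices = fragments$backbone[[i]]))
}

#' Check isotopic steady state across sampling points
#'
#' Compares MID collections measured at increasing cell densities; at
#' isotopic steady state the labeling patterns are time-invariant.
#'
#' @param mid_sets list (one per sampling point) of named lists of MID
#'   vectors over the same fragments.
#' @param tol maximum tolerated absolute deviation (mol fraction).
#' @return list with `max_deviation`, `is_steady`, and the worst fragment.
#' @export
check_isotopic_steady_state <- function(mid_sets, tol = 0.01) {
  if (length(mid_sets) < 2L) stop("need at least two MID collections", call. = FALSE)
  frags <- sort(names(mid_sets[[1]]))
  for (s in mid_sets)
    if (!identical(sort(names(s)), frags))
      stop("fragment-set mismatch between collections", call. = FALSE)
  worst <- 0; worst_frag <- NA_character_
  for (f in frags) {
    for (i in seq_along(mid_sets)) for (j in seq_along(mid_sets)) {
      if (j <= i) next
      d <- max(abs(mid_sets[[i]][[f]] - mid_sets[[j]][[f]]))
      if (d > worst) { worst <- d; worst_frag <- f }
    }
  }
  list(max_deviation = worst, is_steady = worst <= tol, worst_fragment = worst_frag)
}
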