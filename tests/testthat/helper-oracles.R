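# Test helpers: toy model builders and a brute-force full-isotopomer
# simulator used as an independent oracle for the EMU cascade.

write_model <- function(lines) {
  path <- tempfile(fileext = ".csv")
  writeLines(c("reaction_id,equation,reversible,kind,cofactors", lines), path)
  path
}

toy_cleavage_net <- function() {
  # branch + cleavage + scrambled reversible route; 3-carbon substrate
  load_network(write_model(c(
    "upt,A (abc) = B (abc),0,measured,",
    "r1,B (abc) = C (ab) + D (c),0,free,",
    "r2,B (abc) = E (abc) | B (abc) = E (cba),1,free,",
    "r3,E (abc) = C (bc) + D (a),0,free,",
    "rc,C (ab) = Cx (ab),0,free,",
    "rd,D (a) = Dx (a),0,free,")))
}

toy_cycle_net <- function() {
  # condensation cycle: one-carbon unit recycles through a 3-carbon pool
  load_network(write_model(c(
    "upt,A (ab) = B (ab),0,measured,",
    "cond,B (ab) + D (c) = C (abc),0,free,",
    "split,C (abc) = D (a) + E (bc),0,free,",
    "sec,E (ab) = Ex (ab),0,free,")))
}

toy_exchange_net <- function() {
  load_network(write_model(c(
    "upt,A (ab) = B (ab),0,measured,",
    "ex,B (ab) = C (ba),1,free,",
    "out,C (ab) = Cx (ab),0,free,")))
}

toy_split_net <- function() {
  # identifiable one-parameter network: positional split read out by a
  # one-carbon fragment
  load_network(write_model(c(
    "tupt,A (ab) = B (ab),0,measured,",
    "p1,B (ab) = P (a) + Q (b),0,free,",
    "p2,B (ab) = P (b) + Q (a),0,free,",
    "sp,P (a) = Px (a),0,free,",
    "sq,Q (a) = Qx (a),0,free,")))
}

toy_fragments <- function(mets, sizes) {
  df <- data.frame(amino_acid = mets, fragment = "f",
                   C = 0L, H = 0L, N = 0L, O = 0L, Si = 0L, S = 0L,
                   stringsAsFactors = FALSE)
  df$backbone <- lapply(sizes, seq_len)
  df$fragment_id <- paste(mets, "f", sep = "_")
  df
}

# ---- brute-force full-isotopomer steady-state simulator ----------------
# Independent of the EMU machinery: iterates the isotopomer balance of
# every non-input metabolite to a fixed point.

oracle_directed <- function(network, fluxes) {
  ids <- names(network$reactions)
  net <- fluxes$net[ids]
  exch <- stats::setNames(numeric(length(ids)), ids)
  if (length(fluxes$exchange)) exch[names(fluxes$exchange)] <- fluxes$exchange
  rev <- vapply(network$reactions, `[[`, TRUE, "reversible")
  list(fwd = stats::setNames(ifelse(rev, pmax(net, 0) + exch, net), ids),
       bwd = stats::setNames(ifelse(rev, pmax(-net, 0) + exch, 0), ids))
}

oracle_isotopomers <- function(network, fluxes, tracer, tol = 1e-14, maxit = 50000) {
  mets <- network$metabolites
  dv <- oracle_directed(network, fluxes)
  state <- list()
  for (i in seq_len(nrow(mets))) {
    m <- mets$id[i]; n <- mets$n_carbons[i]
    if (n == 0) next
    x <- numeric(2^n)
    if (mets$role[i] == "substrate") {
      for (k in seq_along(tracer$patterns)) {
        bits <- as.integer(strsplit(tracer$patterns[k], "")[[1]])
        mask <- sum(bits * 2^(seq_len(n) - 1))
        x[mask + 1] <- x[mask + 1] + tracer$fractions[k]
      }
    } else x[1] <- 1
    state[[m]] <- x
  }
  fixed_roles <- mets$id[mets$role %in% c("substrate", "gas")]

  # precompute production terms: for each variant occurrence of each
  # directed reaction, the mapping product position -> (substrate, pos)
  terms <- list()
  for (rxn in network$reactions) {
    dirs <- if (rxn$reversible) c("f", "b") else "f"
    for (dir in dirs) for (v in rxn$variants) {
      prods <- if (dir == "f") v$products else v$substrates
      subs <- if (dir == "f") v$substrates else v$products
      subs <- Filter(function(s) !is.null(s$atoms), subs)
      for (occ in prods) {
        if (is.null(occ$atoms) || !length(occ$atoms)) next
        mapping <- lapply(occ$atoms, function(l) {
          for (si in seq_along(subs)) {
            p <- which(subs[[si]]$atoms == l)
            if (length(p)) return(c(si, p))
          }
          stop("unmapped product atom in oracle")
        })
        terms[[length(terms) + 1]] <- list(met = occ$met, rxn = rxn$id, dir = dir,
                                           w = rxn$weight, subs = subs,
                                           mapping = mapping)
      }
    }
  }

  prod_dist <- function(term) {
    ns <- vapply(term$subs, function(s) length(s$atoms), integer(1))
    np <- length(term$mapping)
    out <- numeric(2^np)
    # enumerate joint substrate isotopomers
    grids <- lapply(ns, function(n) 0:(2^n - 1))
    joint <- expand.grid(grids)
    for (r in seq_len(nrow(joint))) {
      p <- 1
      for (si in seq_along(ns))
        p <- p * state[[term$subs[[si]]$met]][joint[r, si] + 1]
      if (p == 0) next
      mask <- 0
      for (k in seq_len(np)) {
        mp <- term$mapping[[k]]
        bit <- bitwAnd(joint[r, mp[1]], bitwShiftL(1L, mp[2] - 1L)) > 0
        if (bit) mask <- mask + 2^(k - 1)
      }
      out[mask + 1] <- out[mask + 1] + p
    }
    out
  }

  for (it in seq_len(maxit)) {
    delta <- 0
    newstate <- state
    for (m in names(state)) {
      if (m %in% fixed_roles) next
      tot <- 0; acc <- numeric(length(state[[m]]))
      for (term in terms) {
        if (term$met != m) next
        f <- term$w * (if (term$dir == "f") dv$fwd[[term$rxn]] else dv$bwd[[term$rxn]])
        if (f == 0) next
        tot <- tot + f
        acc <- acc + f * prod_dist(term)
      }
      if (tot == 0) next
      xnew <- acc / tot
      delta <- max(delta, max(abs(xnew - state[[m]])))
      newstate[[m]] <- xnew
    }
    state <- newstate
    if (delta < tol) break
  }
  state
}

oracle_mid <- function(iso, idx) {
  n <- log2(length(iso))
  out <- numeric(length(idx) + 1)
  for (mask in 0:(length(iso) - 1)) {
    shift <- sum(bitwAnd(mask, 2^(idx - 1)) > 0)
    out[shift + 1] <- out[shift + 1] + iso[mask + 1]
  }
  out
}

# random simplex vector
rsimplex <- function(n) { x <- stats::rexp(n); x / sum(x) }
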