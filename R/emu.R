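# Elementary metabolite unit (EMU) decomposition.  An EMU is a metabolite
# together with a subset of its carbon atoms; tracing measured fragments
# back through the atom transitions yields a cascade of balance systems,
# one per EMU size, in which condensation products couple only to
# strictly smaller EMUs.  This reduces steady-state isotopomer balancing
# to a sequence of small linear solves.

#' Canonical key of an EMU (metabolite + carbon index subset)
#' @param met metabolite id.
#' @param idx integer carbon indices.
#' @return the key string, e.g. `"GLU:1.2.3"`, used to index
#'   [simulate_mids()] results.
#' @export
emu_key <- function(met, idx) paste0(met, ":", paste(idx, collapse = "."))

directed_sides <- function(rxn) {
  out <- list(list(dir = "f", from = rxn$variants, side = "products"))
  if (rxn$reversible)
    out <- c(out, list(list(dir = "b", from = rxn$variants, side = "substrates")))
  out
}

#' EMU decomposition of a network for a set of target fragments
#'
#' Traces each target EMU back to the tracer substrate, instantiating only
#' the EMUs actually needed, and organizes them by size for cascade
#' solving.
#'
#' @param network an `mfa_network`.
#' @param targets list of `list(met=, indices=)` entries (carbon indices
#'   are 1-based within the metabolite).
#' @return an `emu_network`: nodes keyed by `"MET:i.j"`, grouped by size.
#' @export
emu_decompose <- function(network, targets) {
  roles <- stats::setNames(network$metabolites$role, network$metabolites$id)
  ncarb <- stats::setNames(network$metabolites$n_carbons, network$metabolites$id)
  nodes <- list()
  queue <- lapply(targets, function(t) list(met = t$met, idx = sort(unique(t$indices))))
  for (t in queue) {
    if (any(t$idx < 1L) || any(t$idx > ncarb[[t$met]]))
      stop(sprintf("invalid carbon subset for '%s'", t$met), call. = FALSE)
  }
  while (length(queue)) {
    cur <- queue[[1]]; queue <- queue[-1]
    key <- emu_key(cur$met, cur$idx)
    if (!is.null(nodes[[key]])) next
    role <- roles[[cur$met]]
    if (role %in% c("substrate", "gas")) {
      nodes[[key]] <- list(met = cur$met, idx = cur$idx, size = length(cur$idx),
                           input = TRUE, terms = list())
      next
    }
    terms <- list()
    for (rxn in network$reactions) {
      for (ds in directed_sides(rxn)) {
        for (v in rxn$variants) {
          prods <- if (ds$dir == "f") v$products else v$substrates
          subs  <- if (ds$dir == "f") v$substrates else v$products
          for (occ in prods) {
            if (occ$met != cur$met || is.null(occ$atoms)) next
            letters <- occ$atoms[cur$idx]
            sources <- list()
            for (s in subs) {
              if (is.null(s$atoms)) next
              pos <- which(s$atoms %in% letters)
              if (length(pos))
                sources[[length(sources) + 1L]] <- list(met = s$met, idx = sort(pos))
            }
            found <- sum(vapply(sources, function(s) length(s$idx), integer(1)))
            if (found != length(letters))
              stop(sprintf("cannot trace EMU %s through reaction '%s'", key, rxn$id),
                   call. = FALSE)
            terms[[length(terms) + 1L]] <- list(rxn = rxn$id, dir = ds$dir,
                                                w = rxn$weight, sources = sources)
            for (s in sources) queue[[length(queue) + 1L]] <- s
          }
        }
      }
    }
    if (!length(terms))
      stop(sprintf("unreachable-EMU error: %s has no producing atom transition", key),
           call. = FALSE)
    nodes[[key]] <- list(met = cur$met, idx = cur$idx, size = length(cur$idx),
                         input = FALSE, terms = terms)
  }
  sizes <- sort(unique(vapply(nodes, `[[`, 0L, "size")))
  by_size <- lapply(sizes, function(k) {
    names(nodes)[vapply(nodes, function(n) n$size == k && !n$input, logical(1))]
  })
  names(by_size) <- as.character(sizes)
  structure(list(nodes = nodes, sizes = sizes, by_size = by_size,
                 targets = lapply(targets, function(t)
                   emu_key(t$met, sort(unique(t$indices))))),
            class = "emu_network")
}

#' @export
print.emu_network <- function(x, ...) {
  cat(sprintf("emu_network: %d EMUs (%d inputs), sizes %s\n",
              length(x$nodes), sum(vapply(x$nodes, `[[`, TRUE, "input")),
              paste(x$sizes, collapse = ",")))
  invisible(x)
}
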