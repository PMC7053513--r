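# Species treated as freely exchanging with the environment: they carry a
# carbon atom map (so reactions stay carbon-balanced) but are never balanced
# and enter labeling simulations unlabeled.  Dissolved CO2 in an aerated
# culture is dominated by outgassing/ingassing, so fixation draws on an
# effectively unlabeled pool.
GAS_SPECIES <- "CO2"

parse_species <- function(txt, rxn_id, line) {
  # "G6P (abcdef)" or bare "X" (untracked sink)
  txt <- trimws(txt)
  m <- regmatches(txt, regexec("^([A-Za-z0-9_]+)\\s*(\\(([a-zA-Z]*)\\))?$", txt))[[1]]
  if (length(m) == 0L || m[2] == "")
    stop(sprintf("model parse error at line %d: cannot parse species '%s' in reaction '%s'",
                 line, txt, rxn_id), call. = FALSE)
  list(met = m[2], atoms = if (m[3] == "") NULL else strsplit(m[4], "")[[1]])
}

parse_side <- function(txt, rxn_id, line) {
  parts <- strsplit(txt, "+", fixed = TRUE)[[1]]
  lapply(parts, parse_species, rxn_id = rxn_id, line = line)
}

parse_equation_variant <- function(txt, rxn_id, line) {
  sides <- strsplit(txt, "=", fixed = TRUE)[[1]]
  if (length(sides) != 2L)
    stop(sprintf("model parse error at line %d: reaction '%s' needs exactly one '=' per variant",
                 line, rxn_id), call. = FALSE)
  list(substrates = parse_side(sides[1], rxn_id, line),
       products   = parse_side(sides[2], rxn_id, line))
}

parse_cofactors <- function(txt) {
  txt <- trimws(txt)
  if (is.na(txt) || txt == "") return(numeric(0))
  parts <- strsplit(txt, ";", fixed = TRUE)[[1]]
  out <- numeric(0)
  for (p in parts) {
    kv <- strsplit(trimws(p), ":", fixed = TRUE)[[1]]
    if (length(kv) != 2L)
      stop(sprintf("cannot parse cofactor entry '%s'", p), call. = FALSE)
    out[trimws(kv[1])] <- as.numeric(kv[2])
  }
  out
}

check_carbon_balance <- function(rxn) {
  for (v in rxn$variants) {
    sub_letters <- unlist(lapply(v$substrates, `[[`, "atoms"))
    prod_letters <- unlist(lapply(v$products, `[[`, "atoms"))
    has_unmapped_prod <- any(vapply(v$products, function(s) is.null(s$atoms), logical(1)))
    if (anyDuplicated(sub_letters))
      stop(sprintf("carbon-imbalance in reaction '%s': duplicated substrate atom letter", rxn$id),
           call. = FALSE)
    if (anyDuplicated(prod_letters))
      stop(sprintf("carbon-imbalance in reaction '%s': duplicated product atom letter", rxn$id),
           call. = FALSE)
    extra <- setdiff(prod_letters, sub_letters)
    if (length(extra))
      stop(sprintf("carbon-imbalance in reaction '%s': product atom(s) %s not present on substrate side",
                   rxn$id, paste(extra, collapse = ",")), call. = FALSE)
    lost <- setdiff(sub_letters, prod_letters)
    if (length(lost) && !has_unmapped_prod)
      stop(sprintf("carbon-imbalance in reaction '%s': substrate atom(s) %s not conserved",
                   rxn$id, paste(lost, collapse = ",")), call. = FALSE)
  }
  invisible(TRUE)
}

#' Load a carbon-mapped metabolic model
#'
#' Reads a reaction model from a CSV file with columns `reaction_id`,
#' `equation`, `reversible`, `kind` and `cofactors`.  Equations use
#' per-occurrence atom maps, e.g. `"G6P (abcdef) = F6P (abcdef)"`; species
#' written without an atom map are untracked sinks (e.g. `BIOMASS`).
#' Alternative atom transitions of equal probability (used for the
#' symmetric molecules succinate and fumarate) are separated by `"|"`.
#' Cofactors are signed counts such as `"NADPH:-1;CO2:1"`.
#'
#' Every reaction is validated for carbon conservation (the multiset of
#' substrate atom letters must cover the product letters, exactly so when
#' no untracked sink is present); metabolite carbon counts must be
#' consistent across reactions.
#'
#' @param path path to the model CSV file.
#' @param substrate id of the tracer substrate. Defaults to the unique
#'   carbon-mapped metabolite that is consumed but never produced.
#' @param uptake_reaction id of the normalization (substrate uptake)
#'   reaction. Defaults to the unique reaction consuming the substrate.
#' @return an object of class `mfa_network`.
#' @export
load_network <- function(path, substrate = NULL, uptake_reaction = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, comment.char = "#",
                        strip.white = TRUE)
  need <- c("reaction_id", "equation", "reversible", "kind")
  if (!all(need %in% names(df)))
    stop("model file must have columns reaction_id, equation, reversible, kind",
         call. = FALSE)
  if (!"cofactors" %in% names(df)) df$cofactors <- ""
  if (anyDuplicated(df$reaction_id))
    stop("duplicated reaction_id in model file", call. = FALSE)

  reactions <- vector("list", nrow(df))
  for (i in seq_len(nrow(df))) {
    id <- df$reaction_id[i]
    variants_txt <- strsplit(df$equation[i], "|", fixed = TRUE)[[1]]
    variants <- lapply(variants_txt, parse_equation_variant, rxn_id = id, line = i + 1L)
    kind <- match.arg(df$kind[i], c("free", "constrained", "measured", "biomass"))
    rxn <- list(id = id,
                reversible = as.logical(as.integer(df$reversible[i])),
                kind = kind,
                cofactors = parse_cofactors(df$cofactors[i]),
                variants = variants,
                weight = 1 / length(variants))
    check_carbon_balance(rxn)
    if (length(variants) > 1L) {
      s1 <- sort(vapply(variants[[1]]$substrates, `[[`, "", "met"))
      for (v in variants[-1]) {
        if (!identical(sort(vapply(v$substrates, `[[`, "", "met")), s1))
          stop(sprintf("reaction '%s': atom-transition variants must share stoichiometry", id),
               call. = FALSE)
      }
    }
    if (rxn$reversible) {
      unmapped <- vapply(variants[[1]]$products, function(s) is.null(s$atoms), logical(1))
      if (any(unmapped))
        stop(sprintf("reaction '%s': reversible reactions must map all products", id),
             call. = FALSE)
    }
    reactions[[i]] <- rxn
  }
  names(reactions) <- df$reaction_id

  # collect metabolites with carbon counts, checking consistency
  ncar <- list()
  produced <- character(0); consumed <- character(0)
  for (rxn in reactions) {
    for (v in rxn$variants) {
      for (s in v$substrates) {
        n <- length(s$atoms)
        if (!is.null(ncar[[s$met]]) && ncar[[s$met]] != n)
          stop(sprintf("unknown-metabolite error: '%s' used with inconsistent carbon count in reaction '%s'",
                       s$met, rxn$id), call. = FALSE)
        ncar[[s$met]] <- n
        consumed <- c(consumed, s$met)
      }
      for (s in v$products) {
        n <- length(s$atoms)
        if (!is.null(s$atoms)) {
          if (!is.null(ncar[[s$met]]) && ncar[[s$met]] != n)
            stop(sprintf("unknown-metabolite error: '%s' used with inconsistent carbon count in reaction '%s'",
                         s$met, rxn$id), call. = FALSE)
          ncar[[s$met]] <- n
        } else if (is.null(ncar[[s$met]])) ncar[[s$met]] <- 0L
        produced <- c(produced, s$met)
      }
    }
  }
  mets <- names(ncar)
  role <- ifelse(mets %in% GAS_SPECIES, "gas",
          ifelse(!(mets %in% produced), "substrate",
          ifelse(!(mets %in% consumed), "sink", "balanced")))
  metabolites <- data.frame(id = mets, n_carbons = unlist(ncar)[mets],
                            role = role, row.names = NULL,
                            stringsAsFactors = FALSE)

  if (is.null(substrate)) {
    cand <- metabolites$id[metabolites$role == "substrate" & metabolites$n_carbons > 0]
    if (length(cand) != 1L)
      stop("cannot infer tracer substrate; pass `substrate=`", call. = FALSE)
    substrate <- cand
  }
  if (is.null(uptake_reaction)) {
    cand <- vapply(reactions, function(r)
      any(vapply(r$variants[[1]]$substrates, `[[`, "", "met") == substrate), logical(1))
    if (sum(cand) != 1L)
      stop("cannot infer uptake reaction; pass `uptake_reaction=`", call. = FALSE)
    uptake_reaction <- names(reactions)[cand]
  }

  net <- structure(list(metabolites = metabolites, reactions = reactions,
                        substrate = substrate, uptake_reaction = uptake_reaction,
                        source = path),
                   class = "mfa_network")
  validate_network(net)
  net
}

#' Validate network structural invariants
#'
#' Checks that every balanced metabolite is both produced and consumed and
#' that cofactor CO2 counts agree with mapped CO2 occurrences in the atom
#' transitions.
#'
#' @param network an `mfa_network`.
#' @return the network, invisibly.
#' @export
validate_network <- function(network) {
  bal <- network$metabolites$id[network$metabolites$role == "balanced"]
  S <- stoichiometric_matrix(network)
  for (m in bal) {
    if (!any(S[m, ] > 0) || !any(S[m, ] < 0))
      stop(sprintf("balanced metabolite '%s' lacks a producing or consuming reaction", m),
           call. = FALSE)
  }
  for (rxn in network$reactions) {
    v <- rxn$variants[[1]]
    mapped_co2 <- sum(vapply(v$products, `[[`, "", "met") %in% GAS_SPECIES) -
      sum(vapply(v$substrates, `[[`, "", "met") %in% GAS_SPECIES)
    cof_co2 <- if ("CO2" %in% names(rxn$cofactors)) rxn$cofactors[["CO2"]] else 0
    if (mapped_co2 != cof_co2)
      warning(sprintf("reaction '%s': cofactor CO2 count (%g) differs from mapped CO2 occurrences (%d)",
                      rxn$id, cof_co2, mapped_co2), call. = FALSE)
  }
  invisible(network)
}

#' Stoichiometric matrix of the balanced metabolites
#'
#' @param network an `mfa_network`.
#' @param metabolites which metabolites to include as rows; defaults to the
#'   balanced ones, in model-file order.
#' @return a numeric matrix with one row per metabolite and one (signed)
#'   column per reaction.
#' @export
stoichiometric_matrix <- function(network,
                                  metabolites = network$metabolites$id[network$metabolites$role == "balanced"]) {
  rxns <- network$reactions
  S <- matrix(0, nrow = length(metabolites), ncol = length(rxns),
              dimnames = list(metabolites, names(rxns)))
  for (j in seq_along(rxns)) {
    v <- rxns[[j]]$variants[[1]]
    for (s in v$substrates)
      if (s$met %in% metabolites) S[s$met, j] <- S[s$met, j] - 1
    for (s in v$products)
      if (s$met %in% metabolites) S[s$met, j] <- S[s$met, j] + 1
  }
  S
}

#' @export
print.mfa_network <- function(x, ...) {
  cat(sprintf("mfa_network: %d metabolites (%d balanced), %d reactions (%d reversible)\n",
              nrow(x$metabolites), sum(x$metabolites$role == "balanced"),
              length(x$reactions), sum(vapply(x$reactions, `[[`, TRUE, "reversible"))))
  cat(sprintf("  tracer substrate: %s; uptake reaction: %s\n", x$substrate, x$uptake_reaction))
  invisible(x)
}

#' Number of carbons of a metabolite
#' @param network an `mfa_network`.
#' @param met metabolite id.
#' @return integer carbon count.
#' @export
n_carbons <- function(network, met) {
  i <- match(met, network$metabolites$id)
  if (is.na(i)) stop(sprintf("unknown-metabolite error: '%s'", met), call. = FALSE)
  network$metabolites$n_carbons[i]
}

#' Path to the shipped B. megaterium central-metabolism model
#'
#' The model is a documented reconstruction covering PTS glucose uptake,
#' glycolysis, the oxidative and non-oxidative pentose phosphate pathway,
#' the full TCA cycle, PEP carboxylase and pyruvate carboxylase
#' anaplerosis, the pyruvate-oxidase overflow route, acetate/lactate/
#' pyruvate/succinate/2-oxoglutarate secretion, net glutamate synthesis,
#' the osmo-adaptive proline branch and the PhaA/PhaB/PhaC PHB branch.
#'
#' @return file path of the model CSV inside the installed package.
#' @export
bmeg_model_file <- function() {
  system.file("extdata", "bmeg_model.csv", package = "osmoflux", mustWork = TRUE)
}

#' Load the shipped B. megaterium model
#' @return an `mfa_network`.
#' @export
bmeg_network <- function() load_network(bmeg_model_file())
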