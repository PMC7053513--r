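# Natural-isotope correction for GC-MS fragments of TBDMS-derivatized
# amino acids.  A correction matrix C maps the carbon-skeleton MID x
# (fractions of molecules with 0..n backbone 13C) to the observed
# mass-shift distribution C x, accounting for natural heavy isotopes of
# every atom in the derivatized fragment ion.

#' Load an isotope abundance table
#'
#' @param path CSV with columns `element`, `mass_shift`, `abundance`.
#'   Defaults to the versioned table shipped with the package.
#' @return named list mapping element to its mass-shift probability vector
#'   (index 1 = shift 0).
#' @export
load_isotope_table <- function(path = system.file("extdata", "isotope_abundances.csv",
                                                  package = "osmoflux", mustWork = TRUE)) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, comment.char = "#")
  out <- list()
  for (el in unique(df$element)) {
    sub <- df[df$element == el, ]
    v <- numeric(max(sub$mass_shift) + 1L)
    v[sub$mass_shift + 1L] <- sub$abundance
    v[1L] <- v[1L] + (1 - sum(v))  # remainder to the light isotope
    out[[el]] <- v
  }
  out
}

#' Load the TBDMS fragment panel
#'
#' @param path CSV with columns `amino_acid`, `fragment`,
#'   `backbone_indices` (a range like `"2-5"`), and element counts
#'   `C,H,N,O,Si,S` of the derivatization (non-backbone) atoms. Defaults
#'   to the shipped panel of \[M-57\] and \[M-159\] fragments for 12
#'   proteinogenic amino acids.
#' @return data frame with a `fragment_id` column (`"ALA_M-57"`, ...) and
#'   a list-column `backbone` of integer index vectors.
#' @export
load_fragment_table <- function(path = system.file("extdata", "fragments_tbdms.csv",
                                                   package = "osmoflux", mustWork = TRUE)) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, comment.char = "#")
  rng <- strsplit(df$backbone_indices, "-", fixed = TRUE)
  df$backbone <- lapply(rng, function(r) seq.int(as.integer(r[1]), as.integer(r[2])))
  df$fragment_id <- paste(df$amino_acid, df$fragment, sep = "_")
  df
}

#' Discrete convolution of two mass distributions
#'
#' The condensation rule for mass isotopomer distributions: the MID of a
#' molecule assembled from two independent parts is the convolution of the
#' parts' MIDs.
#'
#' @param a,b numeric vectors on the probability simplex.
#' @return vector of length `length(a) + length(b) - 1`.
#' @export
convolve_mid <- function(a, b) {
  out <- numeric(length(a) + length(b) - 1L)
  for (i in seq_along(a)) out[i:(i + length(b) - 1L)] <- out[i:(i + length(b) - 1L)] + a[i] * b
  out
}

conv_power <- function(v, n) {
  out <- 1
  for (i in seq_len(n)) out <- convolve_mid(out, v)
  out
}

#' Natural-isotope correction matrix for a derivatized fragment
#'
#' Column `j` (for `j` backbone 13C atoms, `j = 0..n_backbone`) holds the
#' distribution of observed mass shifts: the convolution of the natural
#' isotope distributions of all derivatization atoms and, when
#' `backbone_natural = TRUE` (default), of the remaining `n_backbone - j`
#' backbone carbons at natural 13C abundance.
#'
#' @param frag one row of the fragment table (see [load_fragment_table()]),
#'   or any list with fields `C,H,N,O,Si,S` and `backbone`.
#' @param abundances isotope table from [load_isotope_table()].
#' @param n_obs number of observed mass channels (rows); defaults to
#'   `n_backbone + 4` to capture the Si/O heavy-isotope tail.
#' @param backbone_natural include natural 13C of unlabeled backbone
#'   positions in the columns (the standard convention).
#' @return a `correction_matrix` object: the matrix with attributes
#'   `fragment_id` and `untruncated_colsums`.
#' @export
correction_matrix <- function(frag, abundances = load_isotope_table(),
                              n_obs = NULL, backbone_natural = TRUE) {
  counts <- c(C = frag$C, H = frag$H, N = frag$N, O = frag$O, Si = frag$Si, S = frag$S)
  if (any(counts < 0)) stop("negative element counts", call. = FALSE)
  bb <- if (is.list(frag$backbone)) frag$backbone[[1]] else frag$backbone
  nb <- length(bb)
  if (is.null(n_obs)) n_obs <- nb + 4L
  base <- 1
  for (el in names(counts))
    if (counts[[el]] > 0) base <- convolve_mid(base, conv_power(abundances[[el]], counts[[el]]))
  C <- matrix(0, nrow = n_obs, ncol = nb + 1L)
  for (j in 0:nb) {
    col <- base
    if (backbone_natural && nb - j > 0)
      col <- convolve_mid(col, conv_power(abundances[["C"]], nb - j))
    # shift by j labeled positions, truncate to the observation window
    full <- c(rep(0, j), col)
    C[, j + 1L] <- full[seq_len(n_obs)][seq_len(n_obs)]
    C[is.na(C[, j + 1L]), j + 1L] <- 0
  }
  structure(C, class = c("correction_matrix", "matrix"),
            fragment_id = frag$fragment_id %||% NA_character_,
            n_backbone = nb)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Correct a raw measured MID for natural isotopes
#'
#' Solves `C x ~ raw` by non-negative least squares and renormalizes the
#' solution to the simplex.  When raw standard deviations are supplied the
#' measurement uncertainty is propagated linearly through the
#' pseudo-inverse to per-entry skeleton standard deviations.
#'
#' @param raw observed mass-shift fractions (length >= nrow(C) is
#'   truncated; shorter vectors are zero-padded).
#' @param C a [correction_matrix()].
#' @param sd optional per-entry standard deviations of `raw`.
#' @return list with `mid` (carbon-skeleton MID, length n_backbone+1),
#'   `sd` (propagated, or NULL), and `resid_norm`.
#' @export
correct_mid <- function(raw, C, sd = NULL) {
  n_obs <- nrow(C)
  kappa <- kappa(C, exact = TRUE)
  if (kappa > 1e8)
    stop(sprintf("correction matrix ill-conditioned (condition number %.3g)", kappa),
         call. = FALSE)
  y <- numeric(n_obs)
  y[seq_len(min(n_obs, length(raw)))] <- raw[seq_len(min(n_obs, length(raw)))]
  x <- pracma::lsqnonneg(unclass(C), y)$x
  s <- sum(x)
  if (s <= 0) stop("correction produced an all-zero MID", call. = FALSE)
  mid <- x / s
  sd_out <- NULL
  if (!is.null(sd)) {
    sde <- numeric(n_obs)
    sde[seq_len(min(n_obs, length(sd)))] <- sd[seq_len(min(n_obs, length(sd)))]
    Cp <- solve(crossprod(C), t(unclass(C)))      # pseudo-inverse (full column rank)
    sd_out <- sqrt(rowSums(sweep(Cp, 2, sde, `*`)^2)) / s
  }
  list(mid = mid, sd = sd_out, resid_norm = sqrt(sum((unclass(C) %*% x - y)^2)))
}

#' Forward-apply natural isotopes to a carbon-skeleton MID
#'
#' The inverse operation of [correct_mid()]: computes the raw mass-shift
#' distribution `C x` that a GC-MS instrument would observe for skeleton
#' MID `x`, truncated to the observation window and renormalized.
#'
#' @param skeleton carbon-skeleton MID (length n_backbone+1).
#' @param C a [correction_matrix()].
#' @return raw MID over `nrow(C)` observed mass shifts.
#' @export
uncorrect_mid <- function(skeleton, C) {
  stopifnot(length(skeleton) == ncol(C))
  y <- as.vector(unclass(C) %*% skeleton)
  y / sum(y)
}
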