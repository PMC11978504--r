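# Evaluation metrics: context-shell membership, native sequence recovery,
# chi-angle recovery with wraparound and 180-degree-symmetric equivalence,
# and confidence-recovery calibration. All pure functions of their inputs.

#' Residues whose sidechains lie within a shell of the context atoms
#'
#' A residue is in the shell if any of its sidechain atoms lies within
#' `radius` of any context atom. Sidechain atoms come from (in order of
#' preference) `sidechain_coords`, the structure's parsed sidechain atoms, or
#' the virtual C-beta as a fallback for backbone-only structures.
#'
#' @param structure a [protein_structure].
#' @param context a [context_atoms].
#' @param radius shell radius, Angstrom (5.0 by convention).
#' @param sidechain_coords optional `[L x 14 x 3]` array.
#' @return integer vector of residue positions (possibly empty).
#' @export
context_shell_residues <- function(structure, context, radius = 5.0,
                                   sidechain_coords = NULL) {
  if (!length(context$element)) return(integer(0))
  L <- length(structure$sequence)
  ctx <- context$coords
  in_shell <- logical(L)
  sc <- structure$sidechain_atoms
  for (i in seq_len(L)) {
    pts <- NULL
    if (!is.null(sidechain_coords)) {
      p <- sidechain_coords[i, 5:14, , drop = FALSE]
      dim(p) <- c(10, 3)
      pts <- p[apply(is.finite(p), 1, all), , drop = FALSE]
    }
    if ((is.null(pts) || !nrow(pts)) && !is.null(sc)) {
      w <- sc$residue == i
      if (any(w)) pts <- cbind(sc$x[w], sc$y[w], sc$z[w])
    }
    if (is.null(pts) || !nrow(pts)) {
      if (!structure$residue_mask[i]) next
      pts <- virtual_cbeta(structure$backbone[i, 1, ],
                           structure$backbone[i, 2, ],
                           structure$backbone[i, 3, ])
    }
    dmin <- min(sqrt(outer(rowSums(pts^2), rowSums(ctx^2), "+") -
                     2 * tcrossprod(pts, ctx)))
    in_shell[i] <- is.finite(dmin) && dmin <= radius
  }
  which(in_shell)
}

#' Native sequence recovery over a position set
#'
#' @param designs list of `design_result`s (or integer vectors / a matrix
#'   with one design per row).
#' @param native integer native tokens `[L]`.
#' @param positions positions to score (default all).
#' @return fraction of design-position pairs matching the native token.
#' @export
sequence_recovery <- function(designs, native, positions = NULL) {
  if (is.null(positions)) positions <- seq_along(native)
  if (!length(positions)) return(NA_real_)
  if (is.matrix(designs)) designs <- asplit(designs, 1)
  if (!is.list(designs)) designs <- list(designs)
  seqs <- lapply(designs, function(d) if (is.list(d)) d$sequence else d)
  mean(vapply(seqs, function(s) mean(s[positions] == native[positions]),
              numeric(1)))
}

#' Chi-angle recovery fractions
#'
#' Circular difference within `threshold_deg` of native; for residues with a
#' 180-degree-symmetric terminal chi (ASP chi2, GLU chi3, PHE/TYR chi2) the
#' difference is taken modulo 180 degrees.
#'
#' @param predicted numeric `[L x 4]` chi angles (radians; `chi_set` objects
#'   accepted).
#' @param native numeric `[L x 4]` native chis (radians).
#' @param sequence integer tokens `[L]`.
#' @param threshold_deg recovery threshold, degrees.
#' @return list with `per_chi` (fraction within threshold for chi1..chi4),
#'   `counts` (number of comparable chis per index) and `overall`
#'   (count-weighted average fraction).
#' @export
chi_recovery <- function(predicted, native, sequence, threshold_deg = 10) {
  if (inherits(predicted, "chi_set")) predicted <- predicted$chi
  if (inherits(native, "chi_set")) native <- native$chi
  L <- length(sequence)
  nchi <- chi_count(sequence)
  sym <- symmetric_chi(sequence)
  hits <- integer(4); counts <- integer(4)
  for (i in seq_len(L)) for (k in seq_len(4)) {
    if (nchi[i] < k) next
    p <- predicted[i, k]; nv <- native[i, k]
    if (is.na(p) || is.na(nv)) next
    d <- abs(wrap_angle(p - nv)) * 180 / pi
    if (!is.na(sym[i]) && sym[i] == k) d <- min(d, abs(180 - d))
    counts[k] <- counts[k] + 1L
    if (d <= threshold_deg) hits[k] <- hits[k] + 1L
  }
  per_chi <- ifelse(counts > 0, hits / counts, NA_real_)
  overall <- if (sum(counts) > 0) sum(hits) / sum(counts) else NA_real_
  list(per_chi = per_chi, counts = counts, overall = overall)
}

#' Confidence-recovery calibration
#'
#' Spearman rank correlation between per-protein predicted confidence and
#' realized sequence recovery.
#'
#' @param confidence numeric vector (0-100).
#' @param recovery numeric vector (0-1), same length.
#' @return list with `correlation` (NA with `constant = TRUE` when either
#'   input is constant), `constant`, `n`.
#' @export
confidence_calibration <- function(confidence, recovery) {
  stopifnot(length(confidence) == length(recovery))
  ok <- is.finite(confidence) & is.finite(recovery)
  confidence <- confidence[ok]; recovery <- recovery[ok]
  n <- length(confidence)
  if (n < 2 || stats::sd(confidence) == 0 || stats::sd(recovery) == 0) {
    return(list(correlation = NA_real_, constant = TRUE, n = n))
  }
  list(correlation = stats::cor(confidence, recovery, method = "spearman"),
       constant = FALSE, n = n)
}
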