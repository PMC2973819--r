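#' Pairwise structural similarity by TM-score
#'
#' Structural similarity between two chains is quantified by superposing
#' aligned CA pairs and scoring `TM = (1/L_target) * sum_i 1/(1 + (d_i/d0)^2)`
#' with the length-dependent scale `d0 = max(1.24 (L_target - 15)^(1/3) - 1.8,
#' 0.5)` Angstrom.  The score is 1 for identical structures, ~0.25 for random
#' pairs of compact structures, and values above [TM_FOLD_THRESHOLD] (0.45)
#' indicate the same fold.  The alignment search combines gapless threading,
#' dynamic programming on secondary-structure strings and best-fragment
#' superposition seeds, each refined by iterated superposition/realignment;
#' alignments are strictly sequence-order preserving.
#'
#' @name tmscore
NULL

#' Same-fold TM-score threshold
#'
#' Two structures with TM-score above this value are considered to represent
#' the same fold; used as the default threshold throughout the clustering
#' and coverage analyses.
#' @export
TM_FOLD_THRESHOLD <- 0.45

#' TM-score normalisation length scale
#' @param target_length length of the target (normalising) chain.
#' @return `d0` in Angstrom, clamped below at 0.5.
#' @export
tm_d0 <- function(target_length) {
  max(1.24 * cbrt(target_length - 15) - 1.8, 0.5)
}

#' Optimal rigid superposition of paired points
#'
#' Least-squares rigid superposition (proper rotation only -- reflections are
#' excluded) of point set `P` onto `Q`.
#'
#' @param P,Q numeric matrices (n x 3), n >= 3, same n, not all collinear.
#' @return List with `rotation` (3x3, determinant +1), `center_P`,
#'   `center_Q` (the transform is `(x - center_P) %*% rotation + center_Q`)
#'   and the minimised `rmsd` in Angstrom.
#' @export
kabsch <- function(P, Q) {
  P <- as.matrix(P); Q <- as.matrix(Q)
  if (nrow(P) != nrow(Q)) stopf("point sets differ in size")
  if (nrow(P) < 3) stopf("need at least 3 points")
  Pc <- sweep(P, 2, colMeans(P))
  if (qr(Pc)$rank < 2) stopf("points are collinear; superposition undefined")
  kabsch_cpp(P, Q)
}

#' TM-score of a fixed alignment
#'
#' Maximises the TM-score of the given residue-pair alignment over rigid
#' superpositions (iterated Kabsch on distance-trimmed subsets of the
#' aligned pairs) and reports the RMSD over all aligned pairs under the
#' final superposition.
#'
#' @param A,B [fold_chain] objects.
#' @param pairs integer matrix (n x 2) of aligned residue indices
#'   `(i in A, j in B)`; an empty alignment scores 0 by convention with
#'   undefined (`NA`) RMSD.
#' @param target_length normalisation length (defaults to the length of B).
#' @return List with `tm_score` and `rmsd`.
#' @export
tm_score_aligned <- function(A, B, pairs, target_length = chain_length(B)) {
  pairs <- matrix(as.integer(pairs), ncol = 2)
  if (nrow(pairs) == 0) return(list(tm_score = 0, rmsd = NA_real_))
  if (any(pairs[, 1] < 1) || any(pairs[, 1] > chain_length(A)) ||
      any(pairs[, 2] < 1) || any(pairs[, 2] > chain_length(B)))
    stopf("alignment pairs out of range")
  r <- tm_eval_cpp(ca_xyz(A), ca_xyz(B), pairs, tm_d0(target_length),
                   as.integer(target_length), deep = TRUE)
  list(tm_score = r$tm, rmsd = r$rmsd)
}

ss_codes <- function(ss) {
  match(ss$labels, c("C", "H", "E")) - 1L
}

#' Align two chains and score their similarity
#'
#' Searches for the sequence-order-preserving residue alignment maximising
#' the TM-score.  Initial candidates come from gapless threading at all
#' offsets, dynamic programming on the two secondary-structure strings, and
#' the best 8-residue fragment superposition; each is refined by iterating
#' superposition and distance-matrix dynamic programming (gap penalty
#' `gap`).  The target (normalising) chain is the shorter of the two by
#' default (ties resolve to `A`).
#'
#' @param A,B [fold_chain] objects with at least 10 residues each.
#' @param ssA,ssB optional precomputed [assign_ss] results (computed on the
#'   fly when omitted).
#' @param normalize which chain sets the target length: `"shorter"`
#'   (default), `"A"`, or `"B"`.
#' @param gap dynamic-programming gap penalty (opening = extension).
#' @return An object of class `tm_alignment`: `pairs` (i in A, j in B),
#'   `coverage` (aligned fraction of the target length), `rmsd` (over
#'   aligned CA pairs), `tm_score`, `d0` and `target_length`.
#' @export
align <- function(A, B, ssA = NULL, ssB = NULL,
                  normalize = c("shorter", "A", "B"), gap = -0.6) {
  normalize <- match.arg(normalize)
  LA <- chain_length(A); LB <- chain_length(B)
  if (LA < 10 || LB < 10) stopf("align needs chains of at least 10 residues")
  ssA <- ssA %||% assign_ss(A)
  ssB <- ssB %||% assign_ss(B)
  Lt <- switch(normalize, shorter = min(LA, LB), A = LA, B = LB)
  d0 <- tm_d0(Lt)
  r <- align_search_cpp(ca_xyz(A), ca_xyz(B), ss_codes(ssA), ss_codes(ssB),
                        d0, as.integer(Lt), gap = gap)
  structure(list(pairs = r$pairs, coverage = nrow(r$pairs) / Lt,
                 rmsd = r$rmsd, tm_score = r$tm, d0 = d0,
                 target_length = Lt),
            class = "tm_alignment")
}

#' @export
print.tm_alignment <- function(x, ...) {
  cat(sprintf(
    "<tm_alignment> TM = %.3f, coverage = %.2f, RMSD = %.2f A (L_target = %d, d0 = %.2f A)\n",
    x$tm_score, x$coverage, x$rmsd, x$target_length, x$d0))
  invisible(x)
}

#' Most similar library structure to a target
#'
#' Scans a structure library for the member with the highest TM-score to the
#' target, normalised by the target's length (ties broken by first
#' occurrence).
#'
#' @param target a [fold_chain]; the normalising chain.
#' @param library a non-empty [structure_set].
#' @param ss_target optional precomputed [assign_ss] of the target.
#' @return List with `label`, `index` and the winning `alignment`.
#' @export
best_hit <- function(target, library, ss_target = NULL) {
  if (!inherits(library, "structure_set") || length(library) == 0)
    stopf("library must be a non-empty structure_set")
  ss_target <- ss_target %||% assign_ss(target)
  best <- NULL
  for (i in seq_along(library$chains)) {
    a <- align(target, library$chains[[i]], ssA = ss_target, normalize = "A")
    if (is.null(best) || a$tm_score > best$alignment$tm_score)
      best <- list(label = library$labels[i], index = i, alignment = a)
  }
  best
}
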