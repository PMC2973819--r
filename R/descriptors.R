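#' Contact-based and geometric structure descriptors
#'
#' Two residues are in contact when at least one pair of their heavy atoms
#' lies closer than 3.5 Angstrom (sequence separation of at least `min_sep`
#' residues, default 2, so that peptide-bonded neighbours -- which are
#' always in contact and carry no topology signal -- are excluded).  Contact
#' order (CO) is the mean sequence separation of contacting pairs divided by
#' the chain length; contact locality (CL) is the fraction of contacts with
#' both residues in the same half of the chain (for odd lengths the
#' N-terminal half takes the extra residue).
#'
#' @name descriptors
NULL

#' Residue contact map
#'
#' @param chain a [fold_chain].
#' @param d_cut heavy-atom distance cutoff in Angstrom (default 3.5).
#' @param min_sep minimum sequence separation `j - i` (default 2).
#' @return Object of class `contact_map`: `L`, `pairs` (n x 2, i < j),
#'   `d_cut`, `min_sep`.
#' @export
contact_map <- function(chain, d_cut = 3.5, min_sep = 2) {
  L <- chain_length(chain)
  pairs <- contact_pairs_cpp(chain$xyz, chain$resid, d_cut,
                             as.integer(min_sep))
  structure(list(L = L, pairs = pairs, d_cut = d_cut, min_sep = min_sep),
            class = "contact_map")
}

#' @export
print.contact_map <- function(x, ...) {
  cat(sprintf("<contact_map> L = %d, %d contacts (d < %.2f A, sep >= %d)\n",
              x$L, nrow(x$pairs), x$d_cut, x$min_sep))
  invisible(x)
}

# Build a contact_map directly from a pair list (testing and toy examples).
contact_map_from_pairs <- function(L, pairs, d_cut = 3.5, min_sep = 2) {
  pairs <- matrix(as.integer(pairs), ncol = 2)
  structure(list(L = as.integer(L), pairs = pairs, d_cut = d_cut,
                 min_sep = min_sep), class = "contact_map")
}

#' Split contact counts by chain half
#'
#' Counts `N_N` (both residues in the N-terminal half), `N_C` (both in the
#' C-terminal half) and `N_NC` (one in each); these always sum to the total
#' contact count.
#'
#' @param cmap a [contact_map].
#' @return Named list `N`, `N_N`, `N_C`, `N_NC`.
#' @export
contact_split <- function(cmap) {
  stopifnot(inherits(cmap, "contact_map"))
  half <- ceiling(cmap$L / 2)
  i <- cmap$pairs[, 1]; j <- cmap$pairs[, 2]
  nn <- sum(i <= half & j <= half)
  nc <- sum(i > half & j > half)
  list(N = nrow(cmap$pairs), N_N = nn, N_C = nc,
       N_NC = nrow(cmap$pairs) - nn - nc)
}

#' Contact order
#'
#' Mean sequence separation of contacting residue pairs divided by the chain
#' length; dimensionless, larger for topologies dominated by long-range
#' contacts.
#'
#' @param cmap a [contact_map] with at least one contact.
#' @return `CO = (sum(j - i) / N) / L`.
#' @export
contact_order <- function(cmap) {
  stopifnot(inherits(cmap, "contact_map"))
  if (nrow(cmap$pairs) == 0) stopf("contact order undefined for zero contacts")
  mean(cmap$pairs[, 2] - cmap$pairs[, 1]) / cmap$L
}

#' Contact locality
#'
#' Fraction of contacting residue pairs formed within the same half of the
#' chain: `CL = (N_N + N_C) / N`.
#'
#' @param cmap a [contact_map] with at least one contact.
#' @return Fraction in `[0, 1]`.
#' @export
contact_locality <- function(cmap) {
  stopifnot(inherits(cmap, "contact_map"))
  if (nrow(cmap$pairs) == 0) stopf("contact locality undefined for zero contacts")
  s <- contact_split(cmap)
  (s$N_N + s$N_C) / s$N
}

#' Radius of gyration
#'
#' Root-mean-square distance of the heavy atoms from their unweighted
#' centroid.
#'
#' @param chain a [fold_chain] with at least one atom.
#' @return Rg in Angstrom.
#' @export
radius_of_gyration <- function(chain) {
  X <- chain$xyz
  if (nrow(X) == 0) stopf("chain has no atoms")
  sqrt(mean(rowSums(sweep(X, 2, colMeans(X))^2)))
}

#' Minimum fragment RMSD of query fragments against a reference set
#'
#' Every contiguous `k`-residue backbone fragment (N, CA, C, O atoms) of
#' every query chain is superposed against every `k`-residue fragment of the
#' reference set; the minimum RMSD per query fragment is recorded.
#'
#' @param query,reference [structure_set] objects (or single [fold_chain]s)
#'   whose chains all have at least `k` residues.
#' @param k fragment length in residues (default 5).
#' @return List with `min_rmsd` (one value per query fragment), `mean` and
#'   `median`.
#' @export
fragment_min_rmsd <- function(query, reference, k = 5) {
  as_set <- function(x) if (inherits(x, "fold_chain"))
    structure_set(list(x)) else x
  query <- as_set(query); reference <- as_set(reference)
  if (length(query) == 0 || length(reference) == 0)
    stopf("query and reference must be non-empty")
  frags <- function(set) {
    out <- list()
    for (ch in set$chains) {
      L <- chain_length(ch)
      if (L < k) stopf("all chains must have at least k = %d residues", k)
      for (i in seq_len(L - k + 1))
        out[[length(out) + 1]] <- backbone_xyz(ch, i:(i + k - 1))
    }
    out
  }
  mins <- frag_min_rmsd_cpp(frags(query), frags(reference))
  list(min_rmsd = mins, mean = mean(mins), median = stats::median(mins))
}

#' Per-member descriptor table for a structure set
#'
#' Computes, for every member: chain length, contact count, contact order,
#' contact locality, radius of gyration, secondary content, structural
#' class, and the three collective-variable fragment counts.  CO/CL are `NA`
#' for members without contacts.
#'
#' @param set a [structure_set].
#' @param d_cut,min_sep contact definition (see [contact_map]).
#' @param cv_cutoff RMSD cutoff for [cv_count] (default 1.0 A).
#' @return data.frame with one row per member.
#' @export
descriptor_table <- function(set, d_cut = 3.5, min_sep = 2, cv_cutoff = 1.0) {
  stopifnot(inherits(set, "structure_set"))
  rows <- lapply(seq_along(set$chains), function(i) {
    ch <- set$chains[[i]]
    cm <- contact_map(ch, d_cut, min_sep)
    ss <- assign_ss(ch)
    has <- nrow(cm$pairs) > 0
    data.frame(
      label = set$labels[i], L = chain_length(ch), n_contacts = nrow(cm$pairs),
      co = if (has) contact_order(cm) else NA_real_,
      cl = if (has) contact_locality(cm) else NA_real_,
      rg = radius_of_gyration(ch),
      sec_content = secondary_content(ss),
      ss_class = structural_class(ss),
      cv_alpha = cv_count(ch, "alpha", cv_cutoff)$count,
      cv_antibeta = cv_count(ch, "antiparallel_beta", cv_cutoff)$count,
      cv_parabeta = cv_count(ch, "parallel_beta", cv_cutoff)$count,
      stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
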