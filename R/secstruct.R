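#' Secondary-structure assignment and structure-based descriptors
#'
#' Secondary structure is assigned from backbone hydrogen-bond geometry in
#' the classic electrostatic approximation: amide hydrogens are rebuilt
#' geometrically (1.0 A from N, anti-bisecting the C(prev)-N-CA frame), the
#' bond energy is
#' `E = 0.084 * (1/r_ON + 1/r_CH - 1/r_OH - 1/r_CN) * 332 kcal/mol`,
#' and a bond exists when `E < -0.5` kcal/mol.  Helix (H) comes from
#' consecutive i+4 -> i turn bonds (runs of at least 4 residues), strand (E)
#' from ladders of bonded bridges (runs of at least 2, with parallel or
#' antiparallel sense recorded), and everything else is coil (C).  The rarer
#' 8-state classes (3-10/pi helix, isolated bridge, turns, bends) are
#' deliberately collapsed to C: only H/E content and class labels feed the
#' downstream analysis.
#'
#' @name secstruct
NULL

KS_HBOND_ENERGY_CUTOFF <- -0.5

# Reconstructed amide H positions (L x 3; row 1 is NA -- no preceding C).
amide_h <- function(chain) {
  L <- chain_length(chain)
  N <- atom_xyz(chain, "N"); CA <- atom_xyz(chain, "CA")
  C <- atom_xyz(chain, "C")
  H <- matrix(NA_real_, L, 3)
  for (i in 2:L) {
    d <- unit(unit(N[i, ] - C[i - 1, ]) + unit(N[i, ] - CA[i, ]))
    H[i, ] <- N[i, ] + d
  }
  H
}

# Kabsch-Sander style electrostatic H-bond energy (kcal/mol) for explicit
# donor (N, H) / acceptor (C, O) coordinates.
ks_energy <- function(Nd, Hd, Ca, Oa) {
  r <- function(a, b) sqrt(sum((a - b)^2))
  0.084 * (1 / r(Oa, Nd) + 1 / r(Ca, Hd) - 1 / r(Oa, Hd) - 1 / r(Ca, Nd)) * 332
}

# Count bonded donor/acceptor pairs between two residue groups given their
# backbone coordinate blocks; used by the synthetic builder to register
# beta-strands.  Each argument is a list with N, H, C, O coordinate matrices
# (rows may contain NA for unavailable H).
count_hbonds_between <- function(grpA, grpB) {
  n <- 0L
  cnt <- function(don, acc) {
    k <- 0L
    for (i in seq_len(nrow(don$N))) {
      if (anyNA(don$H[i, ])) next
      for (j in seq_len(nrow(acc$C))) {
        dca <- sqrt(sum((don$N[i, ] - acc$C[j, ])^2))
        if (dca > 6) next
        if (ks_energy(don$N[i, ], don$H[i, ], acc$C[j, ], acc$O[j, ]) <
            KS_HBOND_ENERGY_CUTOFF) k <- k + 1L
      }
    }
    k
  }
  cnt(grpA, grpB) + cnt(grpB, grpA)
}

# Donor -> acceptor H-bond matrix: HB[d, a] is TRUE when the amide of
# residue d donates to the carbonyl of residue a.
hbond_matrix <- function(chain) {
  L <- chain_length(chain)
  N <- atom_xyz(chain, "N"); C <- atom_xyz(chain, "C")
  O <- atom_xyz(chain, "O"); CA <- atom_xyz(chain, "CA")
  if (anyNA(O)) stopf("assign_ss needs a carbonyl O on every residue")
  H <- amide_h(chain)
  HB <- matrix(FALSE, L, L)
  for (d in 2:L) {
    for (a in seq_len(L)) {
      if (abs(d - a) < 2) next
      if (sum((CA[d, ] - CA[a, ])^2) > 81) next  # 9 A prefilter
      HB[d, a] <- ks_energy(N[d, ], H[d, ], C[a, ], O[a, ]) <
        KS_HBOND_ENERGY_CUTOFF
    }
  }
  HB
}

#' Assign secondary structure from backbone hydrogen bonds
#'
#' @param chain a [fold_chain] with N, CA, C, O on every residue.
#' @return An object of class `ss_assignment`: per-residue `labels` in
#'   `{H, E, C}` and `sheet_sense` (`"parallel"`/`"antiparallel"`, `NA`
#'   outside strands).
#' @export
assign_ss <- function(chain) {
  L <- chain_length(chain)
  HB <- hbond_matrix(chain)
  labels <- rep("C", L)
  sense <- rep(NA_character_, L)

  if (L >= 5) {
    turn4 <- logical(L)
    for (i in seq_len(L - 4)) turn4[i] <- HB[i + 4, i]
    for (i in seq_len(max(0, L - 5))) {
      if (turn4[i] && turn4[i + 1]) labels[(i + 1):(i + 4)] <- "H"
    }
  }

  hb <- function(d, a) d >= 1 && a >= 1 && d <= L && a <= L && HB[d, a]
  bridge <- matrix(0L, L, L)  # 1 parallel, 2 antiparallel
  for (i in seq_len(L)) {
    for (j in seq_len(L)) {
      if (j < i + 3) next
      par <- (hb(j, i - 1) && hb(i + 1, j)) || (hb(i, j - 1) && hb(j + 1, i))
      anti <- (hb(j, i) && hb(i, j)) ||
        (hb(j + 1, i - 1) && hb(i + 1, j - 1))
      if (par) bridge[i, j] <- 1L
      else if (anti) bridge[i, j] <- 2L
    }
  }
  for (i in seq_len(L)) {
    for (j in seq_len(L)) {
      if (bridge[i, j] == 0L) next
      for (r in c(i, j)) {
        if (labels[r] == "H") next
        labels[r] <- "E"
        sense[r] <- if (bridge[i, j] == 1L) "parallel" else "antiparallel"
      }
    }
  }

  # enforce minimum strand run length of 2
  rl <- rle(labels)
  pos <- cumsum(rl$lengths) - rl$lengths + 1
  for (k in seq_along(rl$values)) {
    if (rl$values[k] == "E" && rl$lengths[k] < 2) {
      labels[pos[k]] <- "C"
      sense[pos[k]] <- NA_character_
    }
  }
  structure(list(labels = labels, sheet_sense = sense),
            class = "ss_assignment")
}

#' @export
print.ss_assignment <- function(x, ...) {
  cat(paste(x$labels, collapse = ""), "\n")
  invisible(x)
}

#' Fraction of residues in regular secondary structure
#' @param ss an `ss_assignment`.
#' @return `(n_H + n_E) / L`, a fraction in `[0, 1]`.
#' @export
secondary_content <- function(ss) {
  stopifnot(inherits(ss, "ss_assignment"))
  mean(ss$labels != "C")
}

#' Coarse structural class from H/E content
#'
#' All-alpha when the helix fraction is at least 0.25 with under 5% strand;
#' all-beta symmetrically; alpha/beta when both are at least 5% and total
#' secondary content reaches 30%; coil otherwise.  The 0.25/0.05 split
#' thresholds are package conventions.
#'
#' @param ss an `ss_assignment`.
#' @return One of `"all_alpha"`, `"all_beta"`, `"alpha_beta"`, `"coil"`.
#' @export
structural_class <- function(ss) {
  stopifnot(inherits(ss, "ss_assignment"))
  fh <- mean(ss$labels == "H")
  fe <- mean(ss$labels == "E")
  if (fh >= 0.25 && fe < 0.05) return("all_alpha")
  if (fe >= 0.25 && fh < 0.05) return("all_beta")
  if (fh >= 0.05 && fe >= 0.05 && (fh + fe) >= 0.30) return("alpha_beta")
  "coil"
}

#' Count fragments matching ideal secondary-structure blocks
#'
#' Structure-based collective-variable counts: how many windows (helix) or
#' fragment pairs (sheets) of the chain superpose onto an ideal
#' secondary-structure block below an RMSD cutoff.  `alpha` scans all
#' 6-consecutive-residue windows against an ideal helix block;
#' `antiparallel_beta` and `parallel_beta` scan pairs of 3-residue fragments
#' (`j >= i + 4` antiparallel, `j >= i + 3` parallel, non-overlapping)
#' against ideal two-strand blocks.  Backbone N, CA, C, O atoms enter the
#' superposition; counting is hard (no switching function).
#'
#' @param chain a [fold_chain] with at least 6 residues.
#' @param kind `"alpha"`, `"antiparallel_beta"` or `"parallel_beta"`.
#' @param cutoff RMSD cutoff in Angstrom (default 1.0).
#' @return List with `kind`, `count` and `cutoff`.
#' @export
cv_count <- function(chain, kind = c("alpha", "antiparallel_beta",
                                     "parallel_beta"), cutoff = 1.0) {
  kind <- match.arg(kind)
  L <- chain_length(chain)
  if (L < 6) stopf("cv_count needs at least 6 residues")
  block <- cv_ideal_block(kind)
  count <- 0L
  if (kind == "alpha") {
    for (i in seq_len(L - 5)) {
      frag <- backbone_xyz(chain, i:(i + 5))
      if (kabsch_cpp(frag, block)$rmsd < cutoff) count <- count + 1L
    }
  } else {
    min_gap <- if (kind == "antiparallel_beta") 4L else 3L
    for (i in seq_len(L)) {
      if (i + 2 > L) break
      jmin <- i + min_gap
      if (jmin + 2 > L) next
      for (j in jmin:(L - 2)) {
        frag <- rbind(backbone_xyz(chain, i:(i + 2)),
                      backbone_xyz(chain, j:(j + 2)))
        if (kabsch_cpp(frag, block)$rmsd < cutoff) count <- count + 1L
      }
    }
  }
  list(kind = kind, count = count, cutoff = cutoff)
}

# Ideal reference blocks for cv_count, built from the same internal-coordinate
# generator as the synthetic structures (see .beta_block_geometry for the
# frozen inter-strand placement).
cv_ideal_block <- local({
  cache <- list()
  function(kind) {
    if (!is.null(cache[[kind]])) return(cache[[kind]])
    blk <- if (kind == "alpha") {
      backbone_xyz(build_sse("helix", 6), 1:6)
    } else {
      two_strand_block(parallel = kind == "parallel_beta")
    }
    cache[[kind]] <<- blk
    blk
  }
})
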