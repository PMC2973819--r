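#' Synthetic protein-like structure generators
#'
#' Deterministic generators of compact ~60-residue backbones with known fold
#' ground truth: ideal secondary-structure elements, multi-element folds
#' assembled on a placement grid, self-avoiding random compact chains, pools
#' of mutually dissimilar folds, and revisiting exploration trajectories over
#' such a pool.  Backbones are grown in internal coordinates with standard
#' bond lengths and angles (no force field); side chains are limited to an
#' ideally placed CB.
#'
#' @name synthetic_structures
NULL

.IDEAL_DIHEDRALS <- list(helix = c(-57, -47), strand = c(-139, 135))

# Assemble a fold_chain from build_backbone_cpp output.
chain_from_bb <- function(bb, res_names, cb = TRUE) {
  L <- nrow(bb$N)
  cb <- rep_len(cb, L)
  atoms <- character(0); resid <- integer(0); xyz <- NULL
  rows <- vector("list", L)
  for (i in seq_len(L)) {
    nm <- c("N", "CA", "C", "O", if (cb[i]) "CB")
    m <- rbind(bb$N[i, ], bb$CA[i, ], bb$C[i, ], bb$O[i, ],
               if (cb[i]) bb$CB[i, ])
    rows[[i]] <- list(nm = nm, m = m)
  }
  atoms <- unlist(lapply(rows, `[[`, "nm"))
  resid <- rep(seq_len(L), vapply(rows, function(r) length(r$nm), integer(1)))
  xyz <- do.call(rbind, lapply(rows, `[[`, "m"))
  fold_chain(atoms, resid, xyz, res_names)
}

#' Build an ideal secondary-structure element
#'
#' Grows `n_res` residues at the ideal dihedrals -- helix
#' (phi, psi) = (-57, -47), strand (-139, 135) -- with standard backbone
#' geometry; [phi_psi] recovers the target dihedrals to within 0.5 degrees.
#'
#' @param kind `"helix"` or `"strand"`.
#' @param n_res number of residues (at least 3).
#' @param res_name residue name used for the element (default `"VAL"`).
#' @return A [fold_chain] with N, CA, C, O, CB atoms.
#' @export
build_sse <- function(kind = c("helix", "strand"), n_res, res_name = "VAL") {
  kind <- match.arg(kind)
  if (n_res < 3) stopf("an element needs at least 3 residues, got %d", n_res)
  d <- .IDEAL_DIHEDRALS[[kind]]
  bb <- build_backbone_cpp(rep(d[1], n_res), rep(d[2], n_res))
  chain_from_bb(bb, rep(res_name, n_res), cb = TRUE)
}

# Rigid-move a chain into a canonical frame: CA centroid at the origin,
# first-to-last CA direction along +z, the N(1)->CA(1) perpendicular
# component along +x.  Returns the transformed chain.
canonicalize_element <- function(chain) {
  ca <- ca_xyz(chain)
  a <- unit(ca[nrow(ca), ] - ca[1, ])
  v <- atom_xyz(chain, "N")[1, ] - ca[1, ]
  b <- v - sum(v * a) * a
  if (sqrt(sum(b^2)) < 1e-6) b <- cross3(a, c(1, 0, 0))
  b <- unit(b)
  M <- rbind(b, cross3(a, b), a)   # rows are the new x, y, z axes
  cen <- colMeans(ca)
  transform_chain(chain, R = t(M), t = -colMeans(ca %*% t(M)))
}

rot_z <- function(deg) {
  th <- deg * pi / 180
  matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3, 3,
         byrow = TRUE)
}
rot_x_pi <- matrix(c(1, 0, 0, 0, -1, 0, 0, 0, -1), 3, 3, byrow = TRUE)

# Frozen inter-strand geometry for ideal two-strand blocks: azimuth of the
# partner strand about its own axis, offsets (dx, dy, dz) of its centre, and
# whether it is flipped antiparallel.  Calibrated once by maximising the
# number of backbone hydrogen bonds between two ideal 3-residue strands.
.BETA_BLOCK <- list(
  antiparallel = list(flip = TRUE, azimuth = 340, dx = -0.5, dy = 5.2,
                      dz = -1.0),
  parallel = list(flip = FALSE, azimuth = 40, dx = 0.75, dy = 5.3,
                  dz = -0.25))

# Backbone (N, CA, C, O) coordinates of an ideal two-strand block: residues
# A1..A3 then B1..B3, atom-major within residue.
two_strand_block <- function(parallel = FALSE) {
  p <- .BETA_BLOCK[[if (parallel) "parallel" else "antiparallel"]]
  A <- canonicalize_element(build_sse("strand", 3))
  B <- A
  R <- rot_z(p$azimuth)
  if (p$flip) R <- R %*% rot_x_pi
  B <- transform_chain(B, R = t(R), t = c(p$dx, p$dy, p$dz))
  rbind(backbone_xyz(A), backbone_xyz(B))
}

#' Specify a multi-element fold topology
#'
#' @param elements list of `list(kind = "helix"|"strand", n_res = count)`
#'   entries in sequence order; every element needs at least 3 residues.
#' @param connectivity integer permutation: element `k` in sequence order is
#'   placed at `placement[connectivity[k], ]`.
#' @param placement numeric matrix (one row per element) of grid positions
#'   (Angstrom) for the element axis centres; positions must be pairwise at
#'   least 4 Angstrom apart.
#' @param loop_len loop length (residues) per junction; scalar or vector of
#'   length `n_elements - 1`.
#' @return An object of class `topology_spec`.
#' @export
topology_spec <- function(elements, connectivity, placement, loop_len = 3) {
  K <- length(elements)
  placement <- as.matrix(placement)
  if (ncol(placement) == 2) placement <- cbind(placement, 0)
  if (K < 1) stopf("need at least one element")
  for (el in elements) {
    if (!el$kind %in% c("helix", "strand")) stopf("unknown element kind")
    if (el$n_res < 3) stopf("elements need at least 3 residues")
  }
  if (!identical(sort(as.integer(connectivity)), seq_len(K)))
    stopf("connectivity must be a permutation of 1..%d", K)
  if (nrow(placement) != K) stopf("placement needs one row per element")
  if (K > 1) {
    dd <- as.matrix(stats::dist(placement))
    if (min(dd[upper.tri(dd)]) < 4)
      stopf("placement positions must be pairwise >= 4 A apart")
  }
  loop_len <- rep_len(as.integer(loop_len), max(1, K - 1))
  structure(list(elements = elements, connectivity = as.integer(connectivity),
                 placement = placement, loop_len = loop_len),
            class = "topology_spec")
}

#' Convenience topologies: beta-sheets and helix bundles
#'
#' `topology_sheet` lays `n_strands` strand axes side by side at sheet
#' spacing; `topology_bundle` lays helix axes on a square grid.  With
#' `order = "sequential"` spatially adjacent elements are sequence
#' neighbours (local topology, short loops, low contact order); with
#' `order = "crossover"` the placement order interleaves the sequence
#' (long crossing loops, high contact order).
#'
#' @param n_strands,n_helices number of elements.
#' @param n_res residues per element.
#' @param order `"sequential"` or `"crossover"`.
#' @param spacing axis spacing in Angstrom.
#' @param loop_len residues per connecting loop.
#' @return A [topology_spec].
#' @export
topology_sheet <- function(n_strands = 3, n_res = 6,
                           order = c("sequential", "crossover"),
                           spacing = 5.2, loop_len = NULL) {
  order <- match.arg(order)
  loop_len <- loop_len %||% if (order == "crossover") 4L else 3L
  placement <- cbind(0, spacing * (seq_len(n_strands) - 1), 0)
  conn <- if (order == "sequential") seq_len(n_strands)
          else c(seq(1, n_strands, by = 2), seq(2, n_strands, by = 2))
  elements <- rep(list(list(kind = "strand", n_res = n_res)), n_strands)
  topology_spec(elements, conn, placement, loop_len)
}

#' @rdname topology_sheet
#' @export
topology_bundle <- function(n_helices = 4, n_res = 10,
                            order = c("sequential", "crossover"),
                            spacing = 10, loop_len = NULL) {
  order <- match.arg(order)
  loop_len <- loop_len %||% if (order == "crossover") 5L else 4L
  side <- ceiling(sqrt(n_helices))
  gx <- (seq_len(n_helices) - 1) %% side
  gy <- (seq_len(n_helices) - 1) %/% side
  # serpentine path over the grid so sequential order is spatially adjacent
  gx <- ifelse(gy %% 2 == 1, side - 1 - gx, gx)
  placement <- cbind(spacing * gx, spacing * gy, 0)
  conn <- if (order == "sequential") seq_len(n_helices)
          else c(seq(1, n_helices, by = 2), seq(2, n_helices, by = 2))
  elements <- rep(list(list(kind = "helix", n_res = n_res)), n_helices)
  topology_spec(elements, conn, placement, loop_len)
}

# Backbone groups (N, H, C, O matrices) of a chain for H-bond counting.
hb_groups <- function(chain) {
  list(N = atom_xyz(chain, "N"), H = amide_h(chain),
       C = atom_xyz(chain, "C"), O = atom_xyz(chain, "O"))
}

#' Build a multi-element fold from a topology specification
#'
#' Elements are built at ideal dihedrals, placed rigidly with their axes at
#' the specified grid positions (axis direction alternating to minimise
#' junction gaps), and each element's azimuth (and, for strands, a small
#' axial shift) is chosen to maximise backbone hydrogen bonds to the
#' already-placed elements while avoiding steric clashes.  Junction loops of
#' glycines are laid along arcs between consecutive elements, with
#' randomised arc orientations redrawn (up to 200 times per junction) until
#' no two non-bonded heavy atoms come closer than 2.5 Angstrom.
#' Deterministic given `(spec, seed)`.
#'
#' @param spec a [topology_spec].
#' @param seed integer seed for the loop-placement search.
#' @return A [fold_chain].
#' @export
build_fold <- function(spec, seed = 1) {
  stopifnot(inherits(spec, "topology_spec"))
  withr::with_seed(seed, build_fold_impl(spec))
}

build_fold_impl <- function(spec) {
  K <- length(spec$elements)
  frags <- lapply(spec$elements, function(el) {
    canonicalize_element(build_sse(el$kind, el$n_res))
  })
  pos <- spec$placement[spec$connectivity, , drop = FALSE]

  placed <- list()          # transformed element chains
  placed_xyz <- NULL        # accumulated heavy atoms of placed elements
  dirs <- numeric(K)
  for (k in seq_len(K)) {
    fr <- frags[[k]]
    ext <- {
      ca <- ca_xyz(fr)
      ca[nrow(ca), 3] - ca[1, 3]  # canonical axis is +z
    }
    # axis direction: minimise the gap from the previous element's end
    if (k == 1) {
      dirs[k] <- 1
    } else {
      prev_end <- {
        ca <- ca_xyz(placed[[k - 1]])
        ca[nrow(ca), ]
      }
      gaps <- vapply(c(1, -1), function(d) {
        start <- pos[k, ] + c(0, 0, -d * ext / 2)
        sqrt(sum((start - prev_end)^2))
      }, numeric(1))
      dirs[k] <- c(1, -1)[which.min(gaps)]
    }
    is_strand <- spec$elements[[k]]$kind == "strand"
    azimuths <- if (is_strand) seq(0, 350, by = 10) else seq(0, 330, by = 30)
    shifts <- if (is_strand && k > 1) seq(-1.5, 1.5, by = 0.5) else 0
    best <- NULL
    for (dz in shifts) {
      for (az in azimuths) {
        R <- rot_z(az)
        if (dirs[k] < 0) R <- R %*% rot_x_pi
        cand <- transform_chain(fr, R = t(R), t = pos[k, ] + c(0, 0, dz))
        score <- 0
        if (k > 1) {
          dmat <- pair_dist_min(cand$xyz, placed_xyz)
          n_clash <- sum(dmat < 2.7)
          n_hb <- if (is_strand)
            count_hbonds_between(hb_groups(cand), hb_groups_all(placed))
          else 0L
          score <- 1000 * n_clash - n_hb
        }
        if (is.null(best) || score < best$score)
          best <- list(chain = cand, score = score)
      }
    }
    if (k > 1 && best$score >= 1000)
      stopf("elements %d and earlier clash at any orientation; placements too close",
            k)
    placed[[k]] <- best$chain
    placed_xyz <- rbind(placed_xyz, best$chain$xyz)
  }

  # connect with loops, retrying arc orientations on clashes; clash checks
  # use residue separation in the final numbering so that quasi-bonded
  # neighbours at the junctions are exempt, exactly as in the final chain
  el_len <- vapply(placed, chain_length, integer(1))
  el_start <- cumsum(c(0, (el_len + c(spec$loop_len, 0))[-K]))  # 0-based
  loop_start <- el_start[-K] + el_len[-K]
  # context: every placed element with its final residue numbers
  X_ctx <- do.call(rbind, lapply(placed, `[[`, "xyz"))
  r_ctx <- unlist(lapply(seq_len(K), function(p) placed[[p]]$resid +
                           el_start[p]))
  loops <- vector("list", K - 1)
  for (k in seq_len(max(0, K - 1))) {
    prev_L <- el_len[k]
    e0 <- ca_xyz(placed[[k]])[prev_L, ]
    prev_N <- atom_xyz(placed[[k]], "N")[prev_L, ]
    prev_C <- atom_xyz(placed[[k]], "C")[prev_L, ]
    s1 <- ca_xyz(placed[[k + 1]])[1, ]
    m <- spec$loop_len[k]
    gap <- sqrt(sum((s1 - e0)^2))
    if (gap > 3.9 * (m + 1))
      stopf("junction %d: gap of %.1f A cannot be bridged by %d loop residues",
            k, gap, m)
    loop <- NULL
    for (attempt in seq_len(200)) {
      cand <- loop_candidate(prev_N, prev_CA = e0, prev_C, target = s1,
                             m = m, avoid = colMeans(X_ctx))
      if (is.null(cand)) next
      r_loop <- cand$resid + loop_start[k]
      self <- clash_rg_cpp(cand$xyz, cand$resid, min_res_sep = 2,
                           clash_cut = 2.5)$n_clash
      if (self == 0 &&
          count_clashes_between(cand$xyz, r_loop, X_ctx, r_ctx) == 0) {
        loop <- cand
        break
      }
    }
    if (is.null(loop))
      stopf("junction %d: could not place a clash-free loop in 200 attempts", k)
    loops[[k]] <- loop
    X_ctx <- rbind(X_ctx, loop$xyz)
    r_ctx <- c(r_ctx, r_loop)
  }
  pieces <- list(placed[[1]])
  for (k in seq_len(max(0, K - 1)))
    pieces <- c(pieces, list(loops[[k]]), list(placed[[k + 1]]))

  out <- concat_chains(pieces)
  validate_chain(out)
  cg <- clash_rg_cpp(out$xyz, out$resid, min_res_sep = 2, clash_cut = 2.5)
  if (cg$n_clash > 0)
    stopf("assembled fold has %d residual clashes (min dist %.2f A)",
          cg$n_clash, cg$min_dist)
  out
}

hb_groups_all <- function(chains) {
  gs <- lapply(chains, hb_groups)
  list(N = do.call(rbind, lapply(gs, `[[`, "N")),
       H = do.call(rbind, lapply(gs, `[[`, "H")),
       C = do.call(rbind, lapply(gs, `[[`, "C")),
       O = do.call(rbind, lapply(gs, `[[`, "O")))
}

# Number of atom pairs between two groups closer than `cut` at residue
# separation >= min_sep (residue indices in a common numbering).
count_clashes_between <- function(Xa, ra, Xb, rb, cut = 2.5, min_sep = 2) {
  d2 <- outer(rowSums(Xa^2), rep(1, nrow(Xb))) +
    outer(rep(1, nrow(Xa)), rowSums(Xb^2)) - 2 * Xa %*% t(Xb)
  sep <- abs(outer(ra, rb, "-"))
  sum(d2 < cut^2 & sep >= min_sep)
}

# Per-row minimum distances from rows of A to rows of B.
pair_dist_min <- function(A, B) {
  d2 <- outer(rowSums(A^2), rep(1, nrow(B))) +
    outer(rep(1, nrow(A)), rowSums(B^2)) - 2 * A %*% t(B)
  sqrt(pmax(apply(d2, 1, min), 0))
}

# Rotate points about the axis through `origin` along unit vector `ax` by
# `ang` radians (Rodrigues).
rotate_about <- function(X, origin, ax, ang) {
  Xc <- sweep(X, 2, origin)
  cx <- cbind(ax[2] * Xc[, 3] - ax[3] * Xc[, 2],
              ax[3] * Xc[, 1] - ax[1] * Xc[, 3],
              ax[1] * Xc[, 2] - ax[2] * Xc[, 1])
  dt <- as.vector(Xc %*% ax)
  Xr <- Xc * cos(ang) + cx * sin(ang) + outer(dt, ax) * (1 - cos(ang))
  sweep(Xr, 2, origin, `+`)
}

# Optimal rotation angle about an axis (origin o, unit ax) bringing point p
# as close as possible to distance d_want from q; closed form on the circle
# swept by p.
ccd_angle <- function(p, o, ax, q, d_want) {
  cen <- o + sum((p - o) * ax) * ax
  rv <- p - cen
  r <- sqrt(sum(rv^2))
  if (r < 1e-9) return(0)
  e1 <- rv / r
  e2 <- cross3(ax, e1)
  A <- sum((q - cen) * e1); B <- sum((q - cen) * e2)
  rho <- sqrt(A^2 + B^2)
  if (rho < 1e-12) return(0)
  M <- (r^2 + sum((q - cen)^2) - d_want^2) / (2 * r)
  th0 <- atan2(B, A)
  if (abs(M) <= rho) th0 + acos(max(-1, min(1, M / rho)))
  else if (M > rho) th0       # wanted closer than attainable: get closest
  else th0 + pi               # wanted farther than attainable: get farthest
}

# Cyclic coordinate descent on the loop's phi/psi axes, driving the last CA
# to distance `d_want` from `target`.  Only backbone N/CA/C are updated.
ccd_close <- function(bb, target, d_want = 3.6, tol = 0.4, max_sweeps = 8) {
  m <- nrow(bb$CA)
  obj <- function() abs(sqrt(sum((bb$CA[m, ] - target)^2)) - d_want)
  for (sw in seq_len(max_sweeps)) {
    if (obj() < tol) break
    for (i in seq_len(m)) {
      for (axis in c("phi", "psi")) {
        if (i == m && axis == "psi") next
        if (i == m && axis == "phi") next  # cannot move the last CA
        o <- if (axis == "phi") bb$N[i, ] else bb$CA[i, ]
        p2 <- if (axis == "phi") bb$CA[i, ] else bb$C[i, ]
        ax <- unit(p2 - o)
        best_ang <- ccd_angle(bb$CA[m, ], o, ax, target, d_want)
        if (best_ang != 0) {
          # apply to all atoms distal to the rotated bond
          if (axis == "phi") {
            bb$C[i, ] <- rotate_about(matrix(bb$C[i, ], 1), o, ax,
                                      best_ang)[1, ]
          }
          if (i < m) {
            idx <- (i + 1):m
            bb$N[idx, ] <- rotate_about(bb$N[idx, , drop = FALSE], o, ax,
                                        best_ang)
            bb$CA[idx, ] <- rotate_about(bb$CA[idx, , drop = FALSE], o, ax,
                                         best_ang)
            bb$C[idx, ] <- rotate_about(bb$C[idx, , drop = FALSE], o, ax,
                                        best_ang)
          } else if (axis == "phi") {
            # C of the last residue already rotated above
          }
        }
      }
    }
  }
  bb
}

# Place atom D from reference atoms A-B-C with bond length r, bond angle
# theta at C and torsion chi about B-C (degrees); mirrors the C++ builder.
nerf_r <- function(A, B, C, r, theta, chi) {
  th <- theta * pi / 180; ph <- chi * pi / 180
  bc <- unit(C - B)
  n <- unit(cross3(B - A, bc))
  m <- cross3(n, bc)
  C + bc * (-r * cos(th)) + m * (r * sin(th) * cos(ph)) +
    n * (-r * sin(th) * sin(ph))
}

# Dihedral basins: protein coil states, plus extended states for loops that
# must span long junctions.
.COIL_BASINS <- matrix(c(-75, 145, -120, 130, -90, 0, -60, -30, 60, 45,
                         -57, -47), ncol = 2, byrow = TRUE)
.LOOP_BASINS <- rbind(.COIL_BASINS, c(-139, 135), c(-70, 160))

# One randomised glycine loop candidate of m residues, grown with real
# peptide geometry from the previous residue's N/CA/C.  Dihedrals are
# sampled per residue from loop basins and steered greedily towards
# waypoints on a randomised arc from the previous element's end to the next
# element's start (stronger bulges for tight turns).  Returns NULL when the
# loop end misses the target CA (next element's first residue) by more than
# the virtual-bond band.
loop_candidate <- function(prev_N, prev_CA, prev_C, target, m,
                           n_cand = 12, avoid = NULL) {
  gap <- sqrt(sum((target - prev_CA)^2))
  axis <- if (gap > 1e-6) unit(target - prev_CA) else c(0, 0, 1)
  r <- stats::rnorm(3)
  if (!is.null(avoid) && stats::runif(1) < 0.6) {
    # bias the arc plane away from the occupied region (mixed with fully
    # random directions so blocked corridors can still be threaded)
    away <- (prev_CA + target) / 2 - avoid
    away <- away - sum(away * axis) * axis
    if (sqrt(sum(away^2)) > 1e-6) r <- 1.5 * unit(away) + r
  }
  u <- r - sum(r * axis) * axis
  u <- if (sqrt(sum(u^2)) < 1e-6) unit(cross3(axis, c(1, 0, 0))) else unit(u)
  # virtual CA steps are ~3.8 A, so lay waypoints on an arc whose length
  # matches the walkable path, bulging out as much as needed
  step_target <- stats::runif(1, 3.4, 3.8)
  arc_needed <- step_target * (m + 1)
  bez <- function(h, ts) {
    mid <- (prev_CA + target) / 2 + h * u
    t(vapply(ts, function(t) (1 - t)^2 * prev_CA +
               2 * t * (1 - t) * mid + t^2 * target, numeric(3)))
  }
  arc_of <- function(h) sum(sqrt(rowSums(diff(bez(h, seq(0, 1,
    length.out = 80)))^2)))
  h <- if (arc_needed <= gap * 1.01) stats::runif(1, 0, 0.8)
       else stats::uniroot(function(hh) arc_of(hh) - arc_needed,
                           c(0, arc_needed))$root
  P <- bez(h, seq(0, 1, length.out = 160))
  arc <- c(0, cumsum(sqrt(rowSums(diff(P)^2))))
  wp <- t(vapply(seq_len(m), function(i) {
    P[which.min(abs(arc - arc[length(arc)] * i / (m + 1))), ]
  }, numeric(3)))

  wp_next <- rbind(wp[-1, , drop = FALSE], target)
  N <- matrix(0, m, 3); CA <- matrix(0, m, 3)
  C <- matrix(0, m, 3); O <- matrix(0, m, 3)
  psis <- numeric(m)
  pn <- prev_N; pca <- prev_CA; pc <- prev_C
  for (i in seq_len(m)) {
    # the incoming psi places N/CA, phi orients the carbonyl towards the
    # next waypoint; score all psi x phi combinations from the basin draws
    cand_psi_in <- .LOOP_BASINS[sample.int(nrow(.LOOP_BASINS), n_cand,
                                           replace = TRUE), 2] +
      stats::rnorm(n_cand, 0, 20)
    cand_phi <- .LOOP_BASINS[sample.int(nrow(.LOOP_BASINS), n_cand,
                                        replace = TRUE), 1] +
      stats::rnorm(n_cand, 0, 20)
    best <- NULL
    for (kp in seq_len(n_cand)) {
      Ni <- nerf_r(pn, pca, pc, 1.329, 116.2, cand_psi_in[kp])
      CAi <- nerf_r(pca, pc, Ni, 1.458, 121.7, 180)
      sca <- sum((CAi - wp[i, ])^2)
      c_tgt <- CAi + 1.525 * unit(wp_next[i, ] - CAi)
      for (kf in seq_len(n_cand)) {
        Ci <- nerf_r(pc, Ni, CAi, 1.525, 111.2, cand_phi[kf])
        sc <- sca + sum((Ci - c_tgt)^2)
        if (is.null(best) || sc < best$sc)
          best <- list(sc = sc, N = Ni, CA = CAi, C = Ci,
                       psi_in = cand_psi_in[kp])
      }
    }
    N[i, ] <- best$N; CA[i, ] <- best$CA; C[i, ] <- best$C
    if (i > 1) psis[i - 1] <- best$psi_in
    pn <- best$N; pca <- best$CA; pc <- best$C
  }
  # cyclic-coordinate-descent closure: sweep the loop torsion axes,
  # rotating the distal atoms to bring the terminal CA into the
  # virtual-bond shell of the target
  closed <- ccd_close(list(N = N, CA = CA, C = C), target, d_want = 3.6)
  N <- closed$N; CA <- closed$CA; C <- closed$C
  for (i in seq_len(m)) {
    psi_eff <- if (i < m)
      torsion_angle(N[i, ], CA[i, ], C[i, ], N[i + 1, ]) else 180
    O[i, ] <- nerf_r(N[i, ], CA[i, ], C[i, ], 1.231, 120.5, psi_eff + 180)
  }
  d_end <- sqrt(sum((CA[m, ] - target)^2))
  if (d_end < 2.6 || d_end > 4.3) return(NULL)
  atoms <- rep(c("N", "CA", "C", "O"), m)
  resid <- rep(seq_len(m), each = 4)
  xyz <- do.call(rbind, lapply(seq_len(m), function(i)
    rbind(N[i, ], CA[i, ], C[i, ], O[i, ])))
  fold_chain(atoms, resid, xyz, rep("GLY", m), validate = FALSE)
}

# Concatenate chains into one, renumbering residues contiguously.
concat_chains <- function(chains) {
  off <- 0L
  atoms <- character(0); resid <- integer(0); res_name <- character(0)
  xyz <- NULL
  for (ch in chains) {
    atoms <- c(atoms, ch$atom)
    resid <- c(resid, ch$resid + off)
    res_name <- c(res_name, ch$res_name)
    xyz <- rbind(xyz, ch$xyz)
    off <- off + chain_length(ch)
  }
  fold_chain(atoms, resid, xyz, res_name, validate = FALSE)
}

#' Sample a random compact self-avoiding chain
#'
#' Draws protein-like dihedrals (runs of helix, strand and coil states),
#' then anneals them by greedy pivot moves until the chain is self-avoiding
#' (non-bonded heavy atoms at least 2.5 Angstrom apart) with radius of
#' gyration within 10% of `rg_target`.  Deterministic given `seed`.
#'
#' @param n_res number of residues (at least 5).
#' @param rg_target target radius of gyration in Angstrom (default 11,
#'   typical of compact ~60-residue chains).
#' @param seed integer seed.
#' @param max_moves pivot-move budget per restart.
#' @param max_restarts independent restarts before giving up.
#' @return A [fold_chain] of polyvaline (N, CA, C, O, CB per residue).
#' @export
random_compact_chain <- function(n_res, rg_target = 11, seed = 1,
                                 max_moves = 4000, max_restarts = 6) {
  if (n_res < 5) stopf("need at least 5 residues")
  withr::with_seed(seed, {
    band <- 0.10 * rg_target
    for (restart in seq_len(max_restarts)) {
      dh <- sample_ss_dihedrals(n_res)
      # pivot only at coil positions so the drawn secondary-structure
      # elements survive the collapse (keeps the ensemble protein-like);
      # the annealer widens to all positions if coil moves stagnate
      movable <- which(dh$state == "C")
      if (length(movable) == 0) movable <- seq_len(n_res)
      res <- anneal_chain_cpp(dh$phi, dh$psi, movable, .COIL_BASINS,
                              rg_target, band, max_moves)
      if (res$converged) {
        bb <- build_backbone_cpp(res$phi, res$psi)
        return(chain_from_bb(bb, rep("VAL", n_res), cb = TRUE))
      }
    }
    stopf("no self-avoiding chain with Rg near %.1f A found in %d restarts",
          rg_target, max_restarts)
  })
}

sample_ss_dihedrals <- function(n_res) {
  phi <- numeric(0); psi <- numeric(0); state <- character(0)
  while (length(phi) < n_res) {
    st <- sample(c("H", "E", "C"), 1, prob = c(0.35, 0.20, 0.45))
    len <- if (st == "C") sample(3:6, 1) else sample(5:9, 1)
    if (st == "H") {
      phi <- c(phi, -57 + stats::rnorm(len, 0, 5))
      psi <- c(psi, -47 + stats::rnorm(len, 0, 5))
    } else if (st == "E") {
      phi <- c(phi, -139 + stats::rnorm(len, 0, 10))
      psi <- c(psi, 135 + stats::rnorm(len, 0, 10))
    } else {
      b <- .COIL_BASINS[sample.int(nrow(.COIL_BASINS), len, replace = TRUE), ,
                        drop = FALSE]
      phi <- c(phi, b[, 1] + stats::rnorm(len, 0, 15))
      psi <- c(psi, b[, 2] + stats::rnorm(len, 0, 15))
    }
    state <- c(state, rep(st, len))
  }
  list(phi = phi[seq_len(n_res)], psi = psi[seq_len(n_res)],
       state = state[seq_len(n_res)])
}

chain_energy <- function(phi, psi, rg_target, band) {
  cg <- chain_metrics_cpp(phi, psi, clash_cut = 2.5, min_res_sep = 2)
  ex <- max(0, abs(cg$rg - rg_target) - 0.8 * band)
  list(e = ex^2 + 2 * cg$n_clash, rg = cg$rg, n_clash = cg$n_clash)
}

#' Generate a pool of mutually independent folds
#'
#' Draws [random_compact_chain] candidates and keeps those whose TM-score to
#' every accepted member stays below the same-fold threshold (0.45),
#' guaranteeing a pool of pairwise independent folds.
#'
#' @param K number of folds (at least 1).
#' @param n_res residues per chain.
#' @param seed integer seed.
#' @param rg_target target compactness passed to the chain sampler.
#' @param max_attempts candidate budget.
#' @return A [structure_set] labelled `fold_0..fold_{K-1}`.
#' @export
make_fold_pool <- function(K, n_res = 60, seed = 1, rg_target = 11,
                           max_attempts = max(60, 25 * K)) {
  if (K < 1) stopf("K must be >= 1")
  sub_seeds <- withr::with_seed(seed, sample.int(2^30, max_attempts))
  accepted <- list()
  for (attempt in seq_len(max_attempts)) {
    cand <- random_compact_chain(n_res, rg_target, seed = sub_seeds[attempt])
    ok <- TRUE
    for (ch in accepted) {
      if (align(cand, ch)$tm_score > TM_FOLD_THRESHOLD) { ok <- FALSE; break }
    }
    if (ok) accepted <- c(accepted, list(cand))
    if (length(accepted) == K) break
  }
  if (length(accepted) < K)
    stopf("only %d of %d independent folds found within %d attempts",
          length(accepted), K, max_attempts)
  structure_set(accepted, labels = sprintf("fold_%d", seq_len(K) - 1))
}

#' Specify a revisiting exploration trajectory
#'
#' @param pool_size number of distinct folds in the pool.
#' @param n_frames number of trajectory frames.
#' @param visit_weights per-fold visit probabilities (default uniform); must
#'   be non-negative and sum to 1.
#' @param dt_ps frame spacing in ps (default 60, so that default filtering at
#'   50 ps keeps consecutive frames).
#' @param noise_rmsd per-frame coordinate noise amplitude in Angstrom.
#' @param seed integer seed.
#' @return An object of class `trajectory_spec`.
#' @export
trajectory_spec <- function(pool_size, n_frames, visit_weights = NULL,
                            dt_ps = 60, noise_rmsd = 1.0, seed = 1) {
  visit_weights <- visit_weights %||% rep(1 / pool_size, pool_size)
  if (length(visit_weights) != pool_size)
    stopf("visit_weights length != pool_size")
  if (any(visit_weights < 0) || abs(sum(visit_weights) - 1) > 1e-9)
    stopf("visit_weights must be non-negative and sum to 1")
  if (noise_rmsd < 0) stopf("noise_rmsd must be >= 0")
  structure(list(pool_size = as.integer(pool_size),
                 n_frames = as.integer(n_frames),
                 visit_weights = visit_weights, dt_ps = dt_ps,
                 noise_rmsd = noise_rmsd, seed = as.integer(seed)),
            class = "trajectory_spec")
}

#' Simulate a revisiting exploration trajectory over a fold pool
#'
#' Frame `i` is a copy of a pool fold (drawn i.i.d. from the visit weights)
#' perturbed by i.i.d. Gaussian coordinate noise of overall RMSD
#' `noise_rmsd` (no re-superposition, so the noise includes slight global
#' drift), at timestamp `i * dt_ps`.  Errors if the noise is so large that
#' more than 5% of frames lose same-fold identity (TM-score <= 0.45) to
#' their source fold.
#'
#' @param pool a [structure_set] of size `spec$pool_size`.
#' @param spec a [trajectory_spec].
#' @return List with `trajectory` (a [structure_set] with timestamps) and
#'   `fold_labels` (character, the ground-truth source fold per frame).
#' @export
simulate_trajectory <- function(pool, spec) {
  stopifnot(inherits(spec, "trajectory_spec"))
  if (length(pool) != spec$pool_size)
    stopf("pool size %d != spec pool_size %d", length(pool), spec$pool_size)
  res <- withr::with_seed(spec$seed, {
    f <- sample.int(spec$pool_size, spec$n_frames, replace = TRUE,
                    prob = spec$visit_weights)
    sd <- spec$noise_rmsd / sqrt(3)
    frames <- lapply(seq_len(spec$n_frames), function(i) {
      ch <- pool$chains[[f[i]]]
      if (sd > 0)
        ch$xyz <- ch$xyz + matrix(stats::rnorm(length(ch$xyz), 0, sd),
                                  nrow(ch$xyz), 3)
      ch
    })
    list(f = f, frames = frames)
  })
  traj <- structure_set(res$frames,
                        labels = sprintf("frame_%d", seq_len(spec$n_frames)),
                        time_ps = seq_len(spec$n_frames) * spec$dt_ps)
  if (spec$noise_rmsd > 0) {
    bad <- 0L
    for (i in seq_len(spec$n_frames)) {
      src <- pool$chains[[res$f[i]]]
      L <- chain_length(src)
      tm <- tm_score_aligned(traj$chains[[i]], src, cbind(seq_len(L), seq_len(L)),
                             target_length = L)$tm_score
      if (tm <= TM_FOLD_THRESHOLD) bad <- bad + 1L
    }
    if (bad / spec$n_frames > 0.05)
      stopf("noise_rmsd = %.2f A breaks self-identity for %.0f%% of frames; use a smaller value",
            spec$noise_rmsd, 100 * bad / spec$n_frames)
  }
  list(trajectory = traj, fold_labels = pool$labels[res$f])
}
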