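# Shared fixtures; expensive objects are built once per test run.

.fixtures <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (is.null(.fixtures[[key]])) assign(key, force(expr), envir = .fixtures)
  .fixtures[[key]]
}

# a small ensemble of independent random compact 60-mers
toy_chains <- function(n = 6) {
  memo(sprintf("chains_%d", n),
       lapply(seq_len(n), function(s) random_compact_chain(60, 11, seed = s)))
}

toy_ss <- function(n = 6) {
  memo(sprintf("ss_%d", n), lapply(toy_chains(n), assign_ss))
}

# hand-written 3-residue single-model PDB fixture with known coordinates
fixture_pdb_lines <- function() {
  atoms <- list(
    list(1, "N",  1, -1.200, 0.500, 0.000),
    list(2, "CA", 1,  0.000, 0.000, 0.000),
    list(3, "C",  1,  1.300, 0.600, 0.000),
    list(4, "N",  2,  2.600, 0.500, 0.100),
    list(5, "CA", 2,  3.800, 0.000, 0.000),
    list(6, "C",  2,  5.100, 0.600, 0.000),
    list(7, "N",  3,  6.400, 0.500, 0.100),
    list(8, "CA", 3,  7.600, 0.000, 0.000),
    list(9, "C",  3,  8.900, 0.600, 0.000))
  vapply(atoms, function(a) {
    sprintf("ATOM  %5d  %-3s VAL A%4d    %8.3f%8.3f%8.3f  1.00  0.00",
            a[[1]], a[[2]], a[[3]], a[[4]], a[[5]], a[[6]])
  }, character(1))
}

write_fixture_pdb <- function(path, models = 1) {
  body <- fixture_pdb_lines()
  lines <- if (models == 1) c(body, "END") else {
    unlist(c(lapply(seq_len(models), function(m)
      c(sprintf("MODEL     %4d", m), body, "ENDMDL")), "END"))
  }
  writeLines(lines, path)
  path
}

# minimal artificial chain for contact-geometry tests: `n_res` residues on a
# straight line 20 A apart (no incidental contacts), with optional extra
# atoms appended
sparse_chain <- function(n_res, extra_atoms = NULL, extra_resid = NULL,
                         extra_xyz = NULL) {
  atom <- rep(c("N", "CA", "C"), n_res)
  resid <- rep(seq_len(n_res), each = 3)
  xyz <- do.call(rbind, lapply(seq_len(n_res), function(i) {
    x <- 20 * i
    rbind(c(x - 1.2, 0.5, 0), c(x, 0, 0), c(x + 1.3, 0.6, 0))
  }))
  fold_chain(c(atom, extra_atoms), c(resid, extra_resid),
             rbind(xyz, extra_xyz), rep("VAL", n_res), validate = FALSE)
}

# brute-force contact map oracle: all residue pairs, all heavy-atom pairs
brute_contact_pairs <- function(chain, d_cut = 3.5, min_sep = 2) {
  L <- chain_length(chain)
  out <- NULL
  for (i in seq_len(L - 1)) {
    for (j in (i + 1):L) {
      if (j - i < min_sep) next
      Xi <- chain$xyz[chain$resid == i, , drop = FALSE]
      Xj <- chain$xyz[chain$resid == j, , drop = FALSE]
      hit <- FALSE
      for (a in seq_len(nrow(Xi))) for (b in seq_len(nrow(Xj)))
        if (sqrt(sum((Xi[a, ] - Xj[b, ])^2)) < d_cut) hit <- TRUE
      if (hit) out <- rbind(out, c(i, j))
    }
  }
  if (is.null(out)) matrix(integer(0), 0, 2) else out
}

# independent reference for the greedy max-neighbour clustering: recompute
# neighbour counts from the full matrix at every step
brute_greedy <- function(tm, threshold) {
  n <- nrow(tm)
  alive <- seq_len(n)
  reps <- integer(0)
  assign <- integer(n)
  while (length(alive) > 0) {
    best <- alive[1]; best_cnt <- -1L
    for (v in alive) {
      cnt <- 0L
      for (w in alive) if (w != v && tm[v, w] > threshold) cnt <- cnt + 1L
      if (cnt > best_cnt) { best_cnt <- cnt; best <- v }
    }
    grp <- best
    for (w in alive) if (w != best && tm[best, w] > threshold)
      grp <- c(grp, w)
    assign[grp] <- best
    reps <- c(reps, best)
    alive <- setdiff(alive, grp)
  }
  list(reps = reps, assign = assign)
}

rand_tm_graph <- function(n, seed) {
  withr::with_seed(seed, {
    tm <- matrix(stats::runif(n * n, 0, 0.8), n, n)
    tm[lower.tri(tm)] <- t(tm)[lower.tri(tm)]
    diag(tm) <- 1
    tm
  })
}

rigid_move <- function(chain, angle = 1.1, axis = c(1, 2, 3),
                       shift = c(5, -3, 2)) {
  ax <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, ax[3], -ax[2], -ax[3], 0, ax[1], ax[2], -ax[1], 0), 3, 3)
  R <- diag(3) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
  foldscape:::transform_chain(chain, R = R, t = shift)
}

add_noise <- function(chain, rmsd, seed) {
  withr::with_seed(seed, {
    chain$xyz <- chain$xyz +
      matrix(stats::rnorm(length(chain$xyz), 0, rmsd / sqrt(3)),
             nrow(chain$xyz), 3)
    chain
  })
}

# Trajectory fixture for the frame filter: "good" frames are compact and
# structured (hairpin), "bad" ones fail exactly one criterion -- no
# secondary structure (lone strand) or too large a radius of gyration
# (long straight helix).
filter_fixture <- function() {
  memo("filter_fixture", {
    good <- build_fold(topology_sheet(2, n_res = 6), seed = 1)
    bad_sec <- build_sse("strand", 8)       # all coil, compact enough
    bad_rg <- build_sse("helix", 40)        # highly helical 58 A rod
    stopifnot(secondary_content(assign_ss(good)) > 0.3,
              radius_of_gyration(good) < 15,
              secondary_content(assign_ss(bad_sec)) <= 0.3,
              radius_of_gyration(bad_rg) >= 15)
    chains <- list(bad_sec, good, bad_rg, bad_sec, good, bad_rg, bad_sec,
                   good, good, bad_sec)
    structure_set(chains, labels = sprintf("f%02d", 1:10),
                  time_ps = c(0, 0, 20, 40, 60, 80, 100, 120, 130, 140))
  })
}

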