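#' Fold-space pipeline: filtering, clustering, extrapolation, coverage
#'
#' The analysis stages operate on [structure_set] objects: frames are
#' filtered on secondary content, compactness and time spacing; independent
#' folds are found by greedy maximum-neighbour clustering at the same-fold
#' TM-score threshold; the discovery curve of independent structures versus
#' structures explored is extrapolated with a double-exponential model; and
#' a target set is checked for coverage by a library.
#'
#' @name foldspace_analysis
NULL

#' Filter trajectory frames on structure and time spacing
#'
#' Keeps frames that (i) have secondary content above `min_sec`, (ii) have a
#' radius of gyration below `max_rg`, and (iii) are separated by more than
#' `min_dt` ps from the last kept frame (greedy scan in time order).
#'
#' @param traj a [structure_set]; must carry timestamps when `min_dt > 0`.
#' @param min_sec minimum secondary-content fraction (default 0.30,
#'   exclusive).
#' @param max_rg maximum radius of gyration in Angstrom (default 15,
#'   exclusive).
#' @param min_dt minimum time spacing in ps (default 50, exclusive).
#' @return The filtered [structure_set] (order preserved); may have zero
#'   survivors, in which case a zero-length subset is returned.
#' @export
filter_frames <- function(traj, min_sec = 0.30, max_rg = 15, min_dt = 50) {
  stopifnot(inherits(traj, "structure_set"))
  if (min_dt > 0 && is.null(traj$time_ps))
    stopf("frame timestamps are required when min_dt > 0")
  keep <- logical(length(traj))
  last_t <- -Inf
  for (i in seq_along(traj$chains)) {
    ch <- traj$chains[[i]]
    if (secondary_content(assign_ss(ch)) <= min_sec) next
    if (radius_of_gyration(ch) >= max_rg) next
    if (min_dt > 0 && !(traj$time_ps[i] - last_t > min_dt)) next
    keep[i] <- TRUE
    if (min_dt > 0) last_t <- traj$time_ps[i]
  }
  traj[keep]
}

# Bounded-effort TM neighbour decision for graph construction: the search
# exits as soon as a refined candidate crosses `threshold` (its score is a
# valid lower bound), and abandons pairs whose first refined candidate stays
# more than the safety margin below it.  Validated against the full search;
# used only for thresholded neighbour graphs, never for reported scores.
.TM_GRAPH_MARGIN <- 0.08

tm_graph_score <- function(caA, caB, scA, scB, Lt, threshold) {
  align_search_cpp(caA, caB, scA, scB, tm_d0(Lt), as.integer(Lt),
                   thread_step = 5L, frag_step = 5L, max_iter = 5L,
                   stop_above = threshold,
                   give_up_below = threshold - .TM_GRAPH_MARGIN)$tm
}

# Pairwise same-fold neighbour graph (and TM lower bounds) for a set.
# For equal-length chains the TM-score of a fixed alignment is identical
# under either normalisation, so a single alignment search per pair
# suffices.  When `threshold` is given, an exact shortcut is used: the
# cheap identity-offset alignment provides a lower bound on the searched
# TM-score, so pairs already above the threshold need no full search for
# the thresholded graph.
tm_neighbor_matrix <- function(set, threshold = NULL) {
  n <- length(set)
  sss <- lapply(set$chains, assign_ss)
  if (!is.null(threshold)) {
    scs <- lapply(sss, ss_codes)
    cas <- lapply(set$chains, ca_xyz)
    tm <- tm_graph_cpp(cas, scs, threshold, .TM_GRAPH_MARGIN)
  } else {
    tm <- matrix(1, n, n)
    for (i in seq_len(max(0, n - 1))) {
      for (j in (i + 1):n) {
        val <- align(set$chains[[i]], set$chains[[j]], ssA = sss[[i]],
                     ssB = sss[[j]])$tm_score
        tm[i, j] <- tm[j, i] <- val
      }
    }
  }
  dimnames(tm) <- list(set$labels, set$labels)
  tm
}

#' Greedy maximum-neighbour clustering into independent folds
#'
#' Repeatedly selects the remaining member with the largest number of
#' remaining neighbours (pairs with TM-score above `threshold`), declares it
#' an independent-structure representative, and removes it together with its
#' neighbours, until no members remain.  Ties break to the earliest member.
#'
#' @param set a non-empty [structure_set].
#' @param threshold same-fold TM-score threshold (default
#'   [TM_FOLD_THRESHOLD]).
#' @param tm optional precomputed symmetric TM-score matrix (row/col order
#'   matching the set); computed internally when omitted.
#' @return A `cluster_result`; see [greedy_cluster_matrix].
#' @export
greedy_cluster <- function(set, threshold = TM_FOLD_THRESHOLD, tm = NULL) {
  stopifnot(inherits(set, "structure_set"))
  if (length(set) == 0) stopf("cannot cluster an empty set")
  tm <- tm %||% tm_neighbor_matrix(set, threshold = threshold)
  greedy_cluster_matrix(tm, labels = set$labels, threshold = threshold)
}

#' Greedy maximum-neighbour clustering of a similarity matrix
#'
#' Matrix-level core of [greedy_cluster], usable with any symmetric
#' similarity matrix.
#'
#' @param tm symmetric numeric similarity matrix.
#' @param labels member labels (default from the matrix dimnames).
#' @param threshold similarity threshold defining neighbours.
#' @return Object of class `cluster_result`: `representatives` (ordered as
#'   selected), `assignment` (named character: member -> representative),
#'   `n_independent` and `threshold`.
#' @export
greedy_cluster_matrix <- function(tm, labels = NULL,
                                  threshold = TM_FOLD_THRESHOLD) {
  n <- nrow(tm)
  labels <- labels %||% rownames(tm) %||% sprintf("member_%d", seq_len(n))
  adj <- tm > threshold
  diag(adj) <- FALSE
  remaining <- rep(TRUE, n)
  reps <- integer(0)
  assignment <- integer(n)
  while (any(remaining)) {
    counts <- rep(-1, n)
    counts[remaining] <- colSums(adj[remaining, remaining, drop = FALSE])
    pick <- which.max(counts)  # ties: earliest index
    members <- which(remaining & (adj[pick, ] | seq_len(n) == pick))
    assignment[members] <- pick
    reps <- c(reps, pick)
    remaining[members] <- FALSE
  }
  structure(list(representatives = labels[reps],
                 assignment = stats::setNames(labels[assignment], labels),
                 n_independent = length(reps), threshold = threshold),
            class = "cluster_result")
}

#' @export
print.cluster_result <- function(x, ...) {
  cat(sprintf("<cluster_result> %d independent structures at TM > %.2f\n",
              x$n_independent, x$threshold))
  invisible(x)
}

#' Online discovery curve of independent structures
#'
#' Processes frames in exploration order; a frame is NEW if its TM-score to
#' every previously retained representative is at or below `threshold`, in
#' which case it is retained as a representative.  The cumulative count of
#' retained structures after each frame is the discovery curve; its final
#' value is the number of independent structures explored.
#'
#' @param traj a [structure_set] in exploration order.
#' @param threshold same-fold TM-score threshold.
#' @return data.frame with columns `n_explored`, `n_independent`, and the
#'   representative labels in attribute `"representatives"`.
#' @export
discovery_curve <- function(traj, threshold = TM_FOLD_THRESHOLD) {
  stopifnot(inherits(traj, "structure_set"))
  n <- length(traj)
  reps <- integer(0)
  counts <- integer(n)
  scs <- vector("list", n)
  cas <- lapply(traj$chains, ca_xyz)
  lens <- vapply(traj$chains, chain_length, integer(1))
  get_sc <- function(i) {
    if (is.null(scs[[i]])) scs[[i]] <<- ss_codes(assign_ss(traj$chains[[i]]))
    scs[[i]]
  }
  for (i in seq_len(n)) {
    new <- TRUE
    for (r in reps) {
      Lt <- min(lens[i], lens[r])
      if (lens[i] == lens[r]) {
        idp <- cbind(seq_len(lens[i]), seq_len(lens[i]))
        lb <- tm_eval_cpp(cas[[i]], cas[[r]], idp, tm_d0(Lt), Lt,
                          deep = FALSE)$tm
        if (lb > threshold) { new <- FALSE; break }
      }
      tm <- tm_graph_score(cas[[i]], cas[[r]], get_sc(i), get_sc(r), Lt,
                           threshold)
      if (tm > threshold) { new <- FALSE; break }
    }
    if (new) reps <- c(reps, i)
    counts[i] <- length(reps)
  }
  out <- data.frame(n_explored = seq_len(n), n_independent = counts)
  attr(out, "representatives") <- traj$labels[reps]
  out
}

#' Double-exponential extrapolation of a discovery curve
#'
#' Fits `N_ind(n) = A (1 - exp(-n/tau1)) + B (1 - exp(-n/tau2))` by
#' least squares with multi-start initialisation (tau pairs spanning four
#' decades) and reports the asymptote `A + B`: the number of independent
#' structures that would be discovered in an infinitely long exploration.
#'
#' @param curve data.frame with columns `n_explored`, `n_independent`
#'   (monotone non-decreasing, at least 10 points), as produced by
#'   [discovery_curve].
#' @return Object of class `extrapolation_fit`: `A`, `B`, `tau1`, `tau2`
#'   (`tau1 <= tau2`), `asymptote`, `residual` (root-mean-square fit error).
#' @export
fit_discovery <- function(curve) {
  if (!all(c("n_explored", "n_independent") %in% names(curve)))
    stopf("curve must have columns n_explored and n_independent")
  n <- curve$n_explored; y <- curve$n_independent
  if (length(n) < 10) stopf("need at least 10 curve points")
  if (is.unsorted(y)) stopf("discovery curve must be non-decreasing")
  nmax <- max(n)
  taus <- 10^seq(log10(nmax) - 3, log10(nmax), length.out = 4)
  best <- NULL
  consider <- function(p, rss) {
    if (is.null(best) || rss < best$rss) best <<- list(p = p, rss = rss)
  }
  for (t1 in taus) {
    for (t2 in taus) {
      # the model is linear in (A, B) at fixed taus: solve that exactly,
      # both as a candidate in its own right (covers degenerate curves the
      # nonlinear optimiser cannot move on) and as the nonlinear start
      X <- cbind(1 - exp(-n / t1), 1 - exp(-n / t2))
      ab <- tryCatch(stats::coef(stats::lm.fit(X, y)), error = function(e) NULL)
      if (!is.null(ab)) {
        ab[is.na(ab)] <- 0
        if (all(is.finite(ab))) {
          ab <- pmax(ab, 1e-8)
          rss <- sum((y - X %*% ab)^2)
          consider(c(A = unname(ab[1]), B = unname(ab[2]), tau1 = t1,
                     tau2 = t2), rss)
        }
      }
      start_ab <- if (is.null(ab)) rep(max(y) / 2, 2)
                  else unname(pmax(ab, 1e-8))
      fit <- try(suppressWarnings(minpack.lm::nlsLM(
        y ~ A * (1 - exp(-n / tau1)) + B * (1 - exp(-n / tau2)),
        start = list(A = start_ab[1], B = start_ab[2], tau1 = t1, tau2 = t2),
        lower = c(A = 1e-8, B = 1e-8, tau1 = 1e-8, tau2 = 1e-8),
        upper = c(A = 1e3 * max(y) + 1, B = 1e3 * max(y) + 1,
                  tau1 = 50 * nmax, tau2 = 50 * nmax),
        control = minpack.lm::nls.lm.control(maxiter = 200))),
        silent = TRUE)
      if (inherits(fit, "try-error")) next
      consider(stats::coef(fit), sum(stats::residuals(fit)^2))
    }
  }
  if (is.null(best)) stopf("double-exponential fit failed for all starts")
  p <- best$p
  ord <- order(c(p[["tau1"]], p[["tau2"]]))
  AB <- c(p[["A"]], p[["B"]])[ord]
  tt <- c(p[["tau1"]], p[["tau2"]])[ord]
  structure(list(A = unname(AB[1]), B = unname(AB[2]), tau1 = unname(tt[1]),
                 tau2 = unname(tt[2]), asymptote = unname(sum(AB)),
                 residual = sqrt(best$rss / length(n))),
            class = "extrapolation_fit")
}

#' @export
print.extrapolation_fit <- function(x, ...) {
  cat(sprintf(
    "<extrapolation_fit> asymptote = %.1f (A = %.1f, tau1 = %.3g; B = %.1f, tau2 = %.3g; rms = %.3g)\n",
    x$asymptote, x$A, x$tau1, x$B, x$tau2, x$residual))
  invisible(x)
}

#' Re-discovery histogram of reference structures in a trajectory
#'
#' For each reference structure, counts the number of trajectory frames with
#' TM-score above `threshold` to it; the histogram of these occurrence
#' counts is then averaged over `n_sets` random subsets of `set_size`
#' references, giving a per-bin mean and standard deviation.
#'
#' @param refs reference [structure_set].
#' @param traj trajectory [structure_set].
#' @param threshold same-fold TM-score threshold.
#' @param n_sets number of random reference subsets (default 20).
#' @param set_size references per subset (default 100).
#' @param seed integer seed for the subset draws.
#' @return Object of class `rediscovery_histogram`: `bins` (data.frame with
#'   `n`, `mean_freq`, `sd_freq`), `counts` (per-reference occurrence
#'   counts), `n_sets`, `set_size`.
#' @export
rediscovery_histogram <- function(refs, traj, threshold = TM_FOLD_THRESHOLD,
                                  n_sets = 20, set_size = 100, seed = 1) {
  stopifnot(inherits(refs, "structure_set"), inherits(traj, "structure_set"))
  if (set_size > length(refs))
    stopf("set_size %d exceeds the number of references %d", set_size,
          length(refs))
  counts <- integer(length(refs))
  lens_r <- vapply(refs$chains, chain_length, integer(1))
  lens_t <- vapply(traj$chains, chain_length, integer(1))
  cas_r <- lapply(refs$chains, ca_xyz)
  cas_t <- lapply(traj$chains, ca_xyz)
  sc_r <- lapply(refs$chains, function(ch) ss_codes(assign_ss(ch)))
  sc_t <- lapply(traj$chains, function(ch) ss_codes(assign_ss(ch)))
  for (r in seq_along(refs$chains)) {
    for (t in seq_along(traj$chains)) {
      Lt <- min(lens_r[r], lens_t[t])
      hit <- FALSE
      if (lens_r[r] == lens_t[t]) {
        idp <- cbind(seq_len(Lt), seq_len(Lt))
        hit <- tm_eval_cpp(cas_r[[r]], cas_t[[t]], idp, tm_d0(Lt), Lt,
                           deep = FALSE)$tm > threshold
      }
      if (!hit) {
        hit <- tm_graph_score(cas_r[[r]], cas_t[[t]], sc_r[[r]], sc_t[[t]],
                              Lt, threshold) > threshold
      }
      if (hit) counts[r] <- counts[r] + 1L
    }
  }
  bins <- 0:max(counts)
  freqs <- withr::with_seed(seed, {
    vapply(seq_len(n_sets), function(s) {
      idx <- sample.int(length(refs), set_size)
      tabulate(counts[idx] + 1L, nbins = length(bins)) / set_size
    }, numeric(length(bins)))
  })
  freqs <- matrix(freqs, nrow = length(bins))
  structure(list(
    bins = data.frame(n = bins, mean_freq = rowMeans(freqs),
                      sd_freq = apply(freqs, 1, stats::sd)),
    counts = counts, n_sets = n_sets, set_size = set_size),
    class = "rediscovery_histogram")
}

#' Coverage of a target set by a structure library
#'
#' For each target, finds its best hit in the library (TM-score normalised
#' by the target length) and the first library position at which the target
#' is found (TM-score above `threshold`); reports per-target best hits and
#' the monotone found-fraction curve versus library prefix size
#' (exploration order).
#'
#' @param targets,library non-empty [structure_set] objects.
#' @param threshold found threshold on the TM-score.
#' @return List with `hits` (data.frame: target, best_label, tm, coverage,
#'   rmsd, first_found) and `curve` (data.frame: n_library,
#'   fraction_found).
#' @export
coverage_analysis <- function(targets, library,
                              threshold = TM_FOLD_THRESHOLD) {
  stopifnot(inherits(targets, "structure_set"),
            inherits(library, "structure_set"))
  if (length(targets) == 0 || length(library) == 0)
    stopf("targets and library must be non-empty")
  nt <- length(targets); nl <- length(library)
  ss_t <- lapply(targets$chains, assign_ss)
  rows <- vector("list", nt)
  first_found <- rep(NA_integer_, nt)
  for (ti in seq_len(nt)) {
    best <- NULL
    for (li in seq_len(nl)) {
      a <- align(targets$chains[[ti]], library$chains[[li]], ssA = ss_t[[ti]],
                 normalize = "A")
      if (is.null(best) || a$tm_score > best$a$tm_score)
        best <- list(a = a, li = li)
      if (is.na(first_found[ti]) && a$tm_score > threshold)
        first_found[ti] <- li
    }
    rows[[ti]] <- data.frame(
      target = targets$labels[ti], best_label = library$labels[best$li],
      tm = best$a$tm_score, coverage = best$a$coverage, rmsd = best$a$rmsd,
      first_found = first_found[ti], stringsAsFactors = FALSE)
  }
  hits <- do.call(rbind, rows)
  frac <- vapply(seq_len(nl), function(p)
    mean(!is.na(first_found) & first_found <= p), numeric(1))
  list(hits = hits,
       curve = data.frame(n_library = seq_len(nl), fraction_found = frac))
}

#' Compare descriptor distributions of two structure sets
#'
#' Per descriptor (`co`, `cl`, `rg`, `sec_content`): mean, median and
#' standard deviation in each set, the mean difference (A - B), and the
#' two-sample Kolmogorov-Smirnov distance.  Optionally stratified by
#' structural class; strata empty on either side are skipped with a
#' warning.  Descriptive numbers only -- no significance verdict.
#'
#' @param tabA,tabB descriptor tables from [descriptor_table].
#' @param by_class also stratify by `ss_class`?
#' @return data.frame with one row per (stratum, descriptor).
#' @export
compare_descriptors <- function(tabA, tabB, by_class = FALSE) {
  if (nrow(tabA) == 0 || nrow(tabB) == 0)
    stopf("descriptor tables must be non-empty")
  one <- function(a, b, stratum) {
    do.call(rbind, lapply(c("co", "cl", "rg", "sec_content"), function(v) {
      x <- a[[v]]; y <- b[[v]]
      x <- x[!is.na(x)]; y <- y[!is.na(y)]
      ks <- if (length(x) > 0 && length(y) > 0)
        unname(suppressWarnings(stats::ks.test(x, y)$statistic)) else NA_real_
      data.frame(stratum = stratum, descriptor = v,
                 mean_A = mean(x), mean_B = mean(y),
                 median_A = stats::median(x), median_B = stats::median(y),
                 sd_A = stats::sd(x), sd_B = stats::sd(y),
                 mean_diff = mean(x) - mean(y), ks_distance = ks,
                 stringsAsFactors = FALSE)
    }))
  }
  out <- one(tabA, tabB, "all")
  if (by_class) {
    for (cl in sort(unique(c(tabA$ss_class, tabB$ss_class)))) {
      a <- tabA[tabA$ss_class == cl, , drop = FALSE]
      b <- tabB[tabB$ss_class == cl, , drop = FALSE]
      if (nrow(a) == 0 || nrow(b) == 0) {
        warning(sprintf("class stratum '%s' empty in one set; skipped", cl))
        next
      }
      out <- rbind(out, one(a, b, cl))
    }
  }
  rownames(out) <- NULL
  out
}
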