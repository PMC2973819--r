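test_that("frame filtering applies all three criteria of the selection", {
  traj <- filter_fixture()
  kept <- filter_frames(traj)
  # frames 2, 5, 8 pass content+Rg at >50 ps spacing; frame 9 passes the
  # structural criteria but follows frame 8 within 10 ps
  expect_equal(kept$labels, c("f02", "f05", "f08"))
  expect_equal(kept$time_ps, c(0, 60, 120))
})

test_that("frame filtering is idempotent and order preserving", {
  kept <- filter_frames(filter_fixture())
  again <- filter_frames(kept)
  expect_equal(again$labels, kept$labels)
})

test_that("the time filter is vacuous at min_dt = 0 and demands timestamps otherwise", {
  traj <- filter_fixture()
  good_only <- traj[c(2, 5, 8, 9)]
  all_kept <- filter_frames(good_only, min_dt = 0)
  expect_equal(all_kept$labels, good_only$labels)

  no_time <- structure_set(good_only$chains, labels = good_only$labels)
  expect_error(filter_frames(no_time), "timestamps")
  expect_equal(length(filter_frames(no_time, min_dt = 0)), 4)

  coil <- structure_set(list(build_sse("strand", 8), build_sse("strand", 8)),
                        labels = c("a", "b"), time_ps = c(0, 100))
  expect_length(filter_frames(coil), 0)
})

test_that("greedy clustering follows the max-neighbour rule on a hand graph", {
  tm <- matrix(0.2, 5, 5); diag(tm) <- 1
  tm[1, 2] <- tm[2, 1] <- 0.6
  tm[1, 3] <- tm[3, 1] <- 0.7
  tm[4, 5] <- tm[5, 4] <- 0.5
  labels <- paste0("s", 0:4)
  cl <- greedy_cluster_matrix(tm, labels = labels, threshold = 0.45)
  expect_equal(cl$representatives, c("s0", "s3"))
  expect_equal(unname(cl$assignment[c("s1", "s2")]), c("s0", "s0"))
  expect_equal(unname(cl$assignment["s4"]), "s3")
  expect_equal(unname(cl$assignment["s0"]), "s0")
})

test_that("degenerate similarity graphs cluster as expected", {
  iso <- matrix(0.1, 4, 4); diag(iso) <- 1
  expect_equal(greedy_cluster_matrix(iso, threshold = 0.45)$n_independent, 4)
  full <- matrix(0.9, 4, 4); diag(full) <- 1
  cl <- greedy_cluster_matrix(full, threshold = 0.45)
  expect_equal(cl$n_independent, 1)
  expect_equal(unique(unname(cl$assignment)), cl$representatives)
})

test_that("greedy clustering matches a brute-force reference on random graphs", {
  for (g in seq_len(20)) {
    n <- sample(5:50, 1)
    tm <- rand_tm_graph(n, seed = g)
    got <- greedy_cluster_matrix(tm, threshold = 0.45)
    want <- brute_greedy(tm, threshold = 0.45)
    labels <- sprintf("member_%d", seq_len(n))
    expect_identical(got$representatives, labels[want$reps])
    expect_identical(unname(got$assignment), labels[want$assign])
  }
})

test_that("the discovery curve counts new folds online", {
  pool <- memo("pool5", make_fold_pool(5, 60, seed = 7))
  once <- structure_set(pool$chains, labels = pool$labels)
  dc <- discovery_curve(once)
  expect_equal(dc$n_independent, 1:5)
  expect_equal(attr(dc, "representatives"), pool$labels)

  revisit <- simulate_trajectory(
    pool[1], trajectory_spec(1, 30, noise_rmsd = 0.5, seed = 4))
  dc2 <- discovery_curve(revisit$trajectory)
  expect_equal(tail(dc2$n_independent, 1), 1)
  expect_true(all(diff(dc2$n_independent) >= 0))
})

test_that("double-exponential fits recover generating parameters", {
  n <- 1:5000
  y <- 100 * (1 - exp(-n / 50)) + 50 * (1 - exp(-n / 500))
  fit <- fit_discovery(data.frame(n_explored = n, n_independent = y))
  expect_equal(fit$asymptote, 150, tolerance = 0.01)
  expect_equal(fit$tau1, 50, tolerance = 0.05)
  expect_equal(fit$tau2, 500, tolerance = 0.05)
  expect_lt(fit$residual, 0.1)
})

test_that("a saturated constant curve is the degenerate small-tau limit", {
  fit <- fit_discovery(data.frame(n_explored = 1:100,
                                  n_independent = rep(5, 100)))
  expect_equal(fit$asymptote, 5, tolerance = 0.01)
})

test_that("coupon-collector discovery curves extrapolate to the pool size", {
  K <- 200
  for (seed in 1:5) {
    curve <- withr::with_seed(seed, {
      seen <- integer(0)
      draws <- sample.int(K, 3000, replace = TRUE)
      n_ind <- cumsum(!duplicated(draws))
      data.frame(n_explored = seq_along(draws), n_independent = n_ind)
    })
    fit <- fit_discovery(curve)
    expect_lt(abs(fit$asymptote - K) / K, 0.15)
  }
})

test_that("invalid discovery curves are rejected", {
  expect_error(fit_discovery(data.frame(n_explored = 1:5,
                                        n_independent = 1:5)), "10")
  expect_error(fit_discovery(data.frame(n_explored = 1:20,
                                        n_independent = c(1:19, 5))),
               "non-decreasing")
})

test_that("re-discovery counts match the generator's ground truth", {
  pool <- memo("pool5", make_fold_pool(5, 60, seed = 7))
  refs <- pool[1:2]
  frames <- simulate_trajectory(
    pool[1:2], trajectory_spec(2, 4, visit_weights = c(0.75, 0.25),
                               noise_rmsd = 0.5, seed = 1))
  # this seed draws the visit pattern A,A,A,B
  expect_equal(as.integer(table(frames$fold_labels)[pool$labels[1:2]]),
               c(3L, 1L))
  rh <- rediscovery_histogram(refs, frames$trajectory, n_sets = 5,
                              set_size = 2, seed = 1)
  expect_equal(rh$counts, c(3L, 1L))
  expect_equal(sum(rh$bins$mean_freq), 1, tolerance = 1e-9)
  rh2 <- rediscovery_histogram(refs, frames$trajectory, n_sets = 5,
                               set_size = 2, seed = 1)
  expect_identical(rh2$bins, rh$bins)
})

test_that("references absent from the trajectory score zero everywhere", {
  pool <- memo("pool5", make_fold_pool(5, 60, seed = 7))
  other <- structure_set(toy_chains(3)[2:3], labels = c("x1", "x2"))
  rh <- rediscovery_histogram(other, pool, n_sets = 3, set_size = 2,
                              seed = 2)
  expect_equal(rh$counts, c(0L, 0L))
  expect_equal(rh$bins$mean_freq[rh$bins$n == 0], 1)
  expect_error(rediscovery_histogram(other, pool, set_size = 10), "exceeds")
})

test_that("coverage is complete when targets are contained in the library", {
  pool <- memo("pool5", make_fold_pool(5, 60, seed = 7))
  cov <- coverage_analysis(pool[1:2], pool)
  expect_equal(cov$hits$tm, c(1, 1), tolerance = 1e-6)
  expect_equal(cov$hits$best_label, pool$labels[1:2])
  expect_equal(tail(cov$curve$fraction_found, 1), 1)
  expect_true(all(diff(cov$curve$fraction_found) >= 0))
})

test_that("coverage finds noisy copies but not unrelated folds", {
  pool <- memo("pool5", make_fold_pool(5, 60, seed = 7))
  targets <- structure_set(
    list(add_noise(pool$chains[[1]], 1, 31), add_noise(pool$chains[[2]], 1, 32),
         toy_chains(6)[[6]]),
    labels = c("n1", "n2", "unrelated"))
  cov <- coverage_analysis(targets, pool)
  expect_gte(tail(cov$curve$fraction_found, 1), 2 / 3)
  expect_true(all(cov$hits$tm[1:2] > TM_FOLD_THRESHOLD))

  rnd <- structure_set(toy_chains(6)[5:6], labels = c("r1", "r2"))
  cov0 <- coverage_analysis(rnd, pool[3:5])
  expect_equal(tail(cov0$curve$fraction_found, 1), 0)
})

test_that("descriptor comparison is exact on identical sets and detects CO shifts", {
  pool <- memo("pool5", make_fold_pool(5, 60, seed = 7))
  tab <- memo("tab_pool5", descriptor_table(pool))
  cmp <- compare_descriptors(tab, tab)
  expect_true(all(abs(cmp$mean_diff) < 1e-12))
  expect_true(all(cmp$ks_distance == 0))

  local <- memo("tab_local", descriptor_table(structure_set(list(
    build_fold(topology_sheet(4, 6, "sequential"), 1),
    build_fold(topology_bundle(4, 10, "sequential"), 1),
    build_fold(topology_sheet(5, 6, "sequential"), 1)))))
  cross <- memo("tab_cross", descriptor_table(structure_set(list(
    build_fold(topology_sheet(4, 6, "crossover"), 1),
    build_fold(topology_sheet(4, 6, "crossover"), 2)))))
  cmp2 <- compare_descriptors(local, cross)
  co_row <- cmp2[cmp2$descriptor == "co", ]
  expect_lt(co_row$mean_A, co_row$mean_B)
})

test_that("empty class strata are skipped with a warning", {
  tabA <- data.frame(co = c(0.2, 0.3), cl = c(0.5, 0.6), rg = c(10, 11),
                     sec_content = c(0.4, 0.5),
                     ss_class = c("all_alpha", "all_beta"))
  tabB <- data.frame(co = 0.25, cl = 0.55, rg = 10.5, sec_content = 0.45,
                     ss_class = "all_alpha")
  expect_warning(out <- compare_descriptors(tabA, tabB, by_class = TRUE),
                 "all_beta")
  expect_true("all_alpha" %in% out$stratum)
  expect_false("all_beta" %in% out$stratum)
})
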