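test_that("the contact definition follows the heavy-atom distance threshold", {
  mk <- function(d, sep) {
    # two CB atoms d apart on residues 1 and 1+sep of a sparse chain
    n <- 1 + sep
    sparse_chain(n, extra_atoms = c("CB", "CB"), extra_resid = c(1, n),
                 extra_xyz = rbind(c(0, 30, 0), c(d, 30, 0)))
  }
  expect_true(any(contact_map(mk(3.4, 5))$pairs[, 1] == 1))
  p <- contact_map(mk(3.6, 5))$pairs
  expect_false(any(p[, 1] == 1 & p[, 2] == 6))
  # peptide neighbours are excluded at min_sep = 2 regardless of distance
  p1 <- contact_map(mk(1.0, 1))$pairs
  expect_equal(nrow(p1), 0)
  # but count when the separation filter is relaxed
  p0 <- contact_map(mk(1.0, 1), min_sep = 1)$pairs
  expect_equal(nrow(p0), 1)
})

test_that("contact order and locality reproduce hand-enumerated values", {
  cm <- foldscape:::contact_map_from_pairs(10, rbind(c(1, 10), c(3, 8),
                                                     c(5, 7)))
  expect_equal(contact_order(cm), ((9 + 5 + 2) / 3) / 10)
  expect_equal(contact_order(foldscape:::contact_map_from_pairs(
    10, rbind(c(1, 10)))), 0.9)

  expect_equal(contact_locality(foldscape:::contact_map_from_pairs(
    10, rbind(c(1, 4)))), 1.0)
  expect_equal(contact_locality(foldscape:::contact_map_from_pairs(
    10, rbind(c(3, 8)))), 0.0)
  cm4 <- foldscape:::contact_map_from_pairs(
    10, rbind(c(1, 4), c(6, 9), c(3, 8), c(2, 10)))
  expect_equal(contact_locality(cm4), 0.5)

  empty <- foldscape:::contact_map_from_pairs(10, matrix(integer(0), 0, 2))
  expect_error(contact_order(empty), "undefined")
  expect_error(contact_locality(empty), "undefined")
})

test_that("half-split counts conserve the contact total on random sets", {
  withr::with_seed(42, {
    for (rep in seq_len(1000)) {
      L <- sample(6:40, 1)
      npairs <- sample(1:15, 1)
      i <- sample(seq_len(L - 2), npairs, replace = TRUE)
      j <- pmin(L, i + sample(2:10, npairs, replace = TRUE))
      cm <- foldscape:::contact_map_from_pairs(L, unique(cbind(i, j)))
      s <- contact_split(cm)
      expect_identical(s$N_N + s$N_C + s$N_NC, s$N)
      if (s$N > 0) {
        co <- contact_order(cm)
        expect_gt(co, 0)
        expect_lte(co, (L - 1) / L + 1e-12)
        cl <- contact_locality(cm)
        expect_gte(cl, 0); expect_lte(cl, 1)
      }
    }
  })
})

test_that("contact_map agrees with an all-pairs double-loop oracle", {
  for (seed in 1:3) {
    ch <- random_compact_chain(25, 7.5, seed = seed)
    expect_equal(contact_map(ch)$pairs, brute_contact_pairs(ch),
                 ignore_attr = TRUE)
  }
})

test_that("contact descriptors are invariant under rigid motion", {
  ch <- toy_chains(2)[[1]]
  cm <- contact_map(ch)
  cm2 <- contact_map(rigid_move(ch))
  expect_equal(cm$pairs, cm2$pairs)
  expect_equal(contact_order(cm), contact_order(cm2))
  expect_equal(contact_locality(cm), contact_locality(cm2))
})

test_that("radius of gyration matches hand geometry", {
  one <- fold_chain("CA", 1L, matrix(c(1, 2, 3), 1), "GLY", validate = FALSE)
  expect_equal(radius_of_gyration(one), 0)
  two <- fold_chain(c("CA", "CA"), c(1L, 2L), rbind(c(0, 0, 0), c(4, 0, 0)),
                    c("GLY", "GLY"), validate = FALSE)
  expect_equal(radius_of_gyration(two), 2)
  sq <- fold_chain(rep("CA", 4), 1:4,
                   rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(0, 1, 0)),
                   rep("GLY", 4), validate = FALSE)
  expect_equal(radius_of_gyration(sq), sqrt(0.5))
})

test_that("fragment scan finds exact self-matches and local-geometry matches", {
  ch <- toy_chains(2)[[1]]
  self <- fragment_min_rmsd(ch, ch, k = 5)
  expect_true(all(self$min_rmsd < 1e-9))
  expect_equal(length(self$min_rmsd), 56)

  helices <- structure_set(list(build_sse("helix", 9), build_sse("helix", 14)))
  q <- structure_set(list(build_sse("helix", 7)))
  expect_true(all(fragment_min_rmsd(q, helices, k = 5)$min_rmsd < 0.1))

  strands <- structure_set(list(build_sse("strand", 12)))
  vs <- fragment_min_rmsd(q, strands, k = 5)
  expect_true(all(vs$min_rmsd > 1.5))
  expect_error(fragment_min_rmsd(q, structure_set(list(build_sse("helix", 4))),
                                 k = 5), "k = 5")
})

test_that("descriptor tables cover every member with consistent fields", {
  pool <- memo("pool5", make_fold_pool(5, 60, seed = 7))
  tab <- memo("tab_pool5", descriptor_table(pool))
  expect_equal(nrow(tab), 5)
  expect_equal(tab$label, pool$labels)
  expect_true(all(tab$L == 60))
  expect_true(all(tab$rg > 0 & tab$rg < 15))
  expect_true(all(tab$co > 0 & tab$co <= 1, na.rm = TRUE))
  expect_true(all(tab$cl >= 0 & tab$cl <= 1, na.rm = TRUE))
  expect_true(all(tab$ss_class %in% c("all_alpha", "all_beta", "alpha_beta",
                                      "coil")))
})
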