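euler_R <- function(a) {
  Rz <- function(t) matrix(c(cos(t), sin(t), 0, -sin(t), cos(t), 0, 0, 0, 1),
                           3, 3)
  Ry <- function(t) matrix(c(cos(t), 0, -sin(t), 0, 1, 0, sin(t), 0, cos(t)),
                           3, 3)
  Rz(a[1]) %*% Ry(a[2]) %*% Rz(a[3])
}

# independent superposition oracle: optimal translation is centroid
# matching, so minimise rmsd over a rotation grid refined by optim
oracle_rmsd <- function(P, Q) {
  Pc <- sweep(P, 2, colMeans(P)); Qc <- sweep(Q, 2, colMeans(Q))
  f <- function(a) sqrt(mean(rowSums((Pc %*% euler_R(a) - Qc)^2)))
  grid <- expand.grid(a = seq(0, 2 * pi, 0.4), b = seq(0, pi, 0.4),
                      c = seq(0, 2 * pi, 0.4))
  vals <- apply(grid, 1, f)
  start <- as.numeric(grid[which.min(vals), ])
  stats::optim(start, f, method = "Nelder-Mead",
               control = list(reltol = 1e-14, maxit = 5000))$value
}

test_that("kabsch recovers rigid transformations exactly", {
  withr::with_seed(1, {
    P <- matrix(stats::rnorm(30), 10, 3)
    ang <- pi / 2
    R <- matrix(c(cos(ang), sin(ang), 0, -sin(ang), cos(ang), 0, 0, 0, 1),
                3, 3)
    Q <- P %*% R + matrix(rep(c(1, 2, 3), each = 10), 10, 3)
    k <- kabsch(P, Q)
    expect_lt(k$rmsd, 1e-9)
    expect_equal(k$rotation, R, tolerance = 1e-9, ignore_attr = TRUE)
    moved <- sweep(sweep(P, 2, k$center_P) %*% k$rotation, 2, k$center_Q, `+`)
    expect_equal(moved, Q, tolerance = 1e-9, ignore_attr = TRUE)
  })
})

test_that("kabsch matches a brute-force rotation-grid oracle", {
  P <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0))
  Q <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1.2, 0))
  expect_equal(kabsch(P, Q)$rmsd, oracle_rmsd(P, Q), tolerance = 1e-3)
  withr::with_seed(4, {
    P2 <- matrix(stats::rnorm(15), 5, 3)
    Q2 <- P2 + matrix(stats::rnorm(15, 0, 0.3), 5, 3)
    expect_equal(kabsch(P2, Q2)$rmsd, oracle_rmsd(P2, Q2), tolerance = 1e-3)
  })
})

test_that("reflections are not admitted as superpositions", {
  withr::with_seed(2, {
    P <- matrix(stats::rnorm(24), 8, 3)
    Q <- P %*% diag(c(1, 1, -1))  # mirror image
    k <- kabsch(P, Q)
    expect_gt(k$rmsd, 0.1)
    expect_equal(det(k$rotation), 1, tolerance = 1e-9)
  })
})

test_that("kabsch preconditions are enforced", {
  expect_error(kabsch(matrix(0, 2, 3), matrix(0, 2, 3)), "3 points")
  expect_error(kabsch(matrix(0, 3, 3), matrix(0, 4, 3)), "size")
  line <- cbind(1:5, 0, 0)
  expect_error(kabsch(line, line), "collinear")
})

test_that("self-alignment is exact identity", {
  ch <- toy_chains(2)[[1]]
  a <- align(ch, ch)
  expect_equal(a$tm_score, 1, tolerance = 1e-6)
  expect_equal(a$coverage, 1)
  expect_lt(a$rmsd, 1e-6)
  L <- chain_length(ch)
  s <- tm_score_aligned(ch, ch, cbind(1:L, 1:L), L)
  expect_equal(s$tm_score, 1, tolerance = 1e-6)
})

test_that("the reported TM-score equals the weighted-distance formula", {
  chs <- toy_chains(2)
  A <- chs[[1]]; B <- chs[[2]]
  L <- chain_length(A)
  pairs <- cbind(1:L, 1:L)
  d0 <- tm_d0(L)
  r <- foldscape:::tm_eval_cpp(ca_xyz(A), ca_xyz(B), pairs, d0, L)
  At <- sweep(sweep(ca_xyz(A), 2, r$center_A) %*% r$rotation, 2, r$center_B,
              `+`)
  d <- sqrt(rowSums((At - ca_xyz(B))^2))
  expect_equal(r$tm, mean(1 / (1 + (d / d0)^2)), tolerance = 1e-9)
  # the per-pair weight decreases with distance, so inflating any single
  # distance under a frozen superposition lowers the score
  d2 <- d; d2[7] <- d2[7] + 1
  expect_lt(mean(1 / (1 + (d2 / d0)^2)), mean(1 / (1 + (d / d0)^2)))
})

test_that("empty alignments score zero by convention", {
  chs <- toy_chains(2)
  s <- tm_score_aligned(chs[[1]], chs[[2]], matrix(integer(0), 0, 2), 60)
  expect_equal(s$tm_score, 0)
  expect_true(is.na(s$rmsd))
})

test_that("d0 follows the target-length formula with the short-chain clamp", {
  expect_equal(tm_d0(60), 1.24 * (45)^(1 / 3) - 1.8)
  expect_equal(tm_d0(15), 0.5)
  expect_equal(tm_d0(8), 0.5)
})

test_that("noisy copies of a fold stay clearly above the fold threshold", {
  chs <- toy_chains(3)
  tms <- c()
  for (i in 1:3) for (s in 1:3)
    tms <- c(tms, align(chs[[i]], add_noise(chs[[i]], 1.0, seed = s))$tm_score)
  expect_true(all(tms > 0.7))
})

test_that("TM-score is invariant under rigid motion of either input", {
  chs <- toy_chains(3)
  a0 <- align(chs[[1]], chs[[2]])$tm_score
  expect_equal(align(rigid_move(chs[[1]]), chs[[2]])$tm_score, a0,
               tolerance = 1e-6)
  expect_equal(align(chs[[1]], rigid_move(chs[[2]]))$tm_score, a0,
               tolerance = 1e-6)
})

test_that("alignment is near-symmetric for equal-length chains", {
  chs <- toy_chains(4)
  for (i in 1:3) {
    d <- abs(align(chs[[i]], chs[[i + 1]])$tm_score -
               align(chs[[i + 1]], chs[[i]])$tm_score)
    expect_lt(d, 0.02)
  }
})

test_that("alignment pairs are strictly sequence-order preserving", {
  chs <- toy_chains(4)
  a <- align(chs[[3]], chs[[4]])
  expect_true(all(diff(a$pairs[, 1]) > 0))
  expect_true(all(diff(a$pairs[, 2]) > 0))
  expect_equal(a$coverage, nrow(a$pairs) / a$target_length)
})

test_that("best_hit returns the most similar library member", {
  chs <- toy_chains(6)
  target <- chs[[1]]
  noisy <- add_noise(target, 1.0, seed = 9)
  lib <- structure_set(c(chs[2:6], list(noisy)),
                       labels = c(paste0("r", 1:5), "noisy"))
  hit <- best_hit(target, lib)
  expect_equal(hit$label, "noisy")
  expect_gt(hit$alignment$tm_score, 0.7)

  lib2 <- structure_set(list(target, noisy), labels = c("exact", "noisy"))
  hit2 <- best_hit(target, lib2)
  expect_equal(hit2$label, "exact")
  expect_equal(hit2$alignment$tm_score, 1, tolerance = 1e-6)

  single <- best_hit(target, structure_set(list(chs[[2]]), labels = "only"))
  expect_equal(single$label, "only")
  expect_error(best_hit(target, structure_set(list(chs[[2]]))[0]),
               "non-empty")
})
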