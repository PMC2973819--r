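test_that("a hand-written PDB fixture is parsed field-by-field", {
  f <- withr::local_tempfile(fileext = ".pdb")
  write_fixture_pdb(f)
  set <- read_pdb(f)
  expect_length(set, 1)
  ch <- set$chains[[1]]
  expect_equal(chain_length(ch), 3)
  expect_equal(ca_xyz(ch)[2, ], c(3.8, 0, 0), tolerance = 1e-8)
  expect_equal(atom_xyz(ch, "N")[1, ], c(-1.2, 0.5, 0), tolerance = 1e-8)
  expect_equal(atom_xyz(ch, "C")[3, ], c(8.9, 0.6, 0), tolerance = 1e-8)
  expect_equal(ch$res_name, rep("VAL", 3))
})

test_that("MODEL blocks become separate members and hydrogens are dropped", {
  f <- withr::local_tempfile(fileext = ".pdb")
  write_fixture_pdb(f, models = 2)
  set <- read_pdb(f)
  expect_length(set, 2)
  expect_equal(set$labels, c("model_1", "model_2"))

  fh <- withr::local_tempfile(fileext = ".pdb")
  lines <- fixture_pdb_lines()
  hline <- "ATOM     10  H   VAL A   1      -1.900   1.200   0.000  1.00  0.00"
  writeLines(c(lines, hline, "END"), fh)
  ch <- read_pdb(fh)$chains[[1]]
  expect_false("H" %in% ch$atom)
})

test_that("malformed and incomplete records raise the contracted errors", {
  f <- withr::local_tempfile(fileext = ".pdb")
  lines <- fixture_pdb_lines()
  writeLines(c(lines[1:2], "ATOM      3  C   VAL A   1      junk", lines[-(1:3)],
               "END"), f)
  expect_error(read_pdb(f), "line 3")

  f2 <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(lines[-5], "END"), f2)  # drop CA of residue 2
  expect_error(read_pdb(f2), "residue 2.*CA")

  expect_error(read_pdb(withr::local_tempfile(fileext = ".pdb")), "not found")
})

test_that("alternate locations keep the highest-occupancy copy", {
  f <- withr::local_tempfile(fileext = ".pdb")
  lines <- fixture_pdb_lines()
  alt <- sub("  1.00", "  0.40", sub("^ATOM      2  CA",
                                     "ATOM     99  CA", lines[2]))
  alt <- sub("   0.000   0.000   0.000", "   0.200   0.000   0.000", alt)
  writeLines(c(lines[1], lines[2], alt, lines[-(1:2)], "END"), f)
  ch <- read_pdb(f)$chains[[1]]
  expect_equal(ca_xyz(ch)[1, 1], 0)  # occupancy 1.00 copy wins
})

test_that("write/read round trip preserves coordinates to PDB precision", {
  ch <- build_sse("helix", 8)
  set <- structure_set(list(ch, rigid_move(ch)), labels = c("a", "b"))
  f <- withr::local_tempfile(fileext = ".pdb")
  write_pdb(set, f)
  expect_equal(sum(grepl("^MODEL", readLines(f))), 2)
  back <- read_pdb(f)
  expect_length(back, 2)
  for (m in 1:2)
    expect_equal(back$chains[[m]]$xyz, set$chains[[m]]$xyz,
                 tolerance = 2e-3, ignore_attr = TRUE)
})

test_that("round trip also holds for heterogeneous member layouts", {
  set <- structure_set(list(build_sse("helix", 8), build_sse("strand", 5)),
                       labels = c("h", "s"))
  f <- withr::local_tempfile(fileext = ".pdb")
  write_pdb(set, f)
  back <- read_pdb(f)
  expect_length(back, 2)
  expect_equal(back$chains[[2]]$xyz, set$chains[[2]]$xyz, tolerance = 2e-3,
               ignore_attr = TRUE)
})

test_that("empty or invalid sets are rejected where the contract requires", {
  expect_length(structure_set(list()), 0)
  expect_error(write_pdb(structure_set(list()), withr::local_tempfile()),
               "non-empty")
  expect_error(write_pdb(list(), withr::local_tempfile()), "structure_set")
  expect_error(structure_set(list(build_sse("helix", 4)) |> rep(2),
                             labels = c("x", "x")), "unique")
  expect_error(structure_set(list(build_sse("helix", 4), build_sse("helix", 4)),
                             labels = c("a", "b"), time_ps = c(5, 1)),
               "non-decreasing")
})

test_that("phi/psi recover construction dihedrals and respect conventions", {
  h <- build_sse("helix", 12)
  pp <- phi_psi(h)
  expect_true(all(abs(pp$phi[2:11] - (-57)) < 0.5))
  expect_true(all(abs(pp$psi[2:11] - (-47)) < 0.5))
  expect_true(is.na(pp$phi[1]))
  expect_true(is.na(pp$psi[12]))

  flat <- foldscape:::chain_from_bb(
    build_backbone_cpp(rep(180, 6), rep(180, 6)), rep("VAL", 6))
  ppf <- phi_psi(flat)
  expect_true(all(abs(abs(ppf$phi[2:5]) - 180) < 0.5))
  expect_true(all(abs(abs(ppf$psi[2:5]) - 180) < 0.5))
})

test_that("phi/psi are invariant under rigid motion", {
  ch <- toy_chains(2)[[1]]
  a <- phi_psi(ch)
  b <- phi_psi(rigid_move(ch))
  expect_equal(a$phi[-1], b$phi[-1], tolerance = 1e-6)
  expect_equal(a$psi[-60], b$psi[-60], tolerance = 1e-6)
})

test_that("chain invariants are enforced", {
  ch <- build_sse("helix", 5)
  bad <- ch
  bad$xyz[bad$atom == "CA" & bad$resid == 3, ] <- c(50, 50, 50)
  expect_error(validate_chain(bad), "CA-CA")
  bad2 <- ch
  bad2$xyz[1, 1] <- NaN
  expect_error(validate_chain(bad2), "finite")
})
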