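test_that("RMSD vanishes for identical and rigidly moved frames", {
  set.seed(41)
  frame <- matrix(rnorm(30, sd = 4), 10, 3)
  expect_identical(rmsd(frame, frame, superpose = FALSE), 0)
  R <- random_rotation()
  moved <- sweep(frame %*% t(R), 2, -c(5, -3, 2))
  expect_lt(rmsd(moved, frame, superpose = TRUE), 1e-6)
  expect_gt(rmsd(moved, frame, superpose = FALSE), 1)
})

test_that("superposed RMSD matches an independent quaternion oracle", {
  set.seed(43)
  for (rep in 1:10) {
    a <- matrix(rnorm(30, sd = 3), 10, 3)
    b <- matrix(rnorm(30, sd = 3), 10, 3)
    expect_equal(rmsd(a, b, superpose = TRUE), quaternion_rmsd(a, b),
                 tolerance = 1e-8)
  }
})

test_that("RMSD is symmetric, nonnegative, and superposition never hurts", {
  set.seed(47)
  for (rep in 1:5) {
    a <- matrix(rnorm(24, sd = 2), 8, 3)
    b <- a + matrix(rnorm(24, sd = 0.5), 8, 3)
    s_ab <- rmsd(a, b); s_ba <- rmsd(b, a)
    expect_equal(s_ab, s_ba, tolerance = 1e-10)
    expect_gte(s_ab, 0)
    expect_lte(s_ab, rmsd(a, b, superpose = FALSE) + 1e-12)
  }
  expect_error(rmsd(matrix(0, 4, 3), matrix(0, 5, 3)), "mismatched")
})

test_that("RMSF closed forms hold", {
  ref <- matrix(rnorm(15), 5, 3)
  # static trajectory: zero fluctuation
  static <- trajectory(list(ref, ref, ref))
  expect_equal(rmsf(static), rep(0, 5))
  # two frames displacing atom 1 by +/- d along x: RMSF_1 = d (mean ref)
  d <- 0.7
  f1 <- ref; f1[1, 1] <- ref[1, 1] + d
  f2 <- ref; f2[1, 1] <- ref[1, 1] - d
  out <- rmsf(trajectory(list(f1, f2)), reference_mode = "mean")
  expect_equal(out, c(d, rep(0, 4)))
})

test_that("RMSF of isotropic Gaussian noise approaches sigma * sqrt(3)", {
  ref <- matrix(rnorm(15, sd = 5), 5, 3)
  sigma <- 0.8
  traj <- synthetic_trajectory(ref, sigma = sigma, n_frames = 10000,
                               seed = 99)
  vals <- rmsf(traj, reference_mode = "mean")
  expect_true(all(abs(vals - sigma * sqrt(3)) < 0.03 * sigma * sqrt(3)))
})

test_that("the time-averaged reference minimizes RMSF per atom", {
  traj <- synthetic_trajectory(matrix(rnorm(21), 7, 3), sigma = 0.5,
                               n_frames = 200, seed = 7)
  base <- rmsf(traj, reference_mode = "mean")
  for (rep in 1:5) {
    other <- traj$coords[sample(dim(traj$coords)[1], 1), , ]
    alt <- rmsf(traj, reference_mode = "provided", reference = other)
    expect_true(all(base <= alt + 1e-12))
  }
  first <- rmsf(traj, reference_mode = "first")
  expect_true(all(base <= first + 1e-12))
  expect_error(rmsf(traj, reference_mode = "provided",
                    reference = matrix(0, 3, 3)), "wrong atom count")
})

test_that("synthetic trajectories are seeded, unbiased, and leave the RNG alone", {
  ref <- matrix(rnorm(12), 4, 3)
  frozen <- synthetic_trajectory(ref, sigma = 0, n_frames = 5, seed = 3)
  for (f in 1:5) expect_equal(frozen$coords[f, , ], ref)
  t1 <- synthetic_trajectory(ref, sigma = 0.4, n_frames = 10, seed = 12)
  t2 <- synthetic_trajectory(ref, sigma = 0.4, n_frames = 10, seed = 12)
  expect_identical(t1$coords, t2$coords)
  expect_identical(t1$times, 10 * (0:9))
  # per-atom frame means stay within 4 sigma / sqrt(n) of the reference
  n <- 2000
  t3 <- synthetic_trajectory(ref, sigma = 0.5, n_frames = n, seed = 8)
  means <- apply(t3$coords, c(2, 3), mean)
  expect_true(all(abs(means - ref) < 4 * 0.5 / sqrt(n)))
  # global RNG stream is not consumed
  set.seed(1); before <- rnorm(1)
  set.seed(1); invisible(synthetic_trajectory(ref, 0.1, 3, seed = 77))
  expect_identical(rnorm(1), before)
})

test_that("trajectories round-trip through CSV and multi-model PDB", {
  pep <- build_ideal_helix("MAT")
  ref <- as.matrix(pep$atoms[, c("x", "y", "z")])
  traj <- synthetic_trajectory(ref, sigma = 0.2, n_frames = 3, seed = 5)
  f <- withr::local_tempfile(fileext = ".csv")
  write_trajectory_csv(traj, f)
  back <- read_trajectory_csv(f)
  expect_equal(back$coords, traj$coords, tolerance = 1e-9)
  # multi-model PDB written frame by frame
  fp <- withr::local_tempfile(fileext = ".pdb")
  con <- file(fp, "w")
  for (fr in 1:3) {
    writeLines(sprintf("MODEL     %4d", fr), con)
    p <- set_peptide_coords(pep, traj$coords[fr, , ])
    tmp <- withr::local_tempfile(fileext = ".pdb")
    write_pdb(p, tmp)
    atoms <- grep("^ATOM", readLines(tmp), value = TRUE)
    writeLines(atoms, con)
    writeLines("ENDMDL", con)
  }
  close(con)
  mm <- read_trajectory_pdb(fp)
  expect_identical(dim(mm$coords), dim(traj$coords))
  expect_equal(mm$coords, traj$coords, tolerance = 1e-3, ignore_attr = TRUE)
})

test_that("per-frame RMSD series uses the CA selection", {
  pep <- build_ideal_helix("MATLEK")
  ref <- as.matrix(pep$atoms[, c("x", "y", "z")])
  traj <- synthetic_trajectory(ref, sigma = 0.3, n_frames = 4, seed = 2)
  traj$atom_selection <- ca_indices(pep)
  series <- rmsd_series(traj, reference = ref[ca_indices(pep), ])
  expect_identical(nrow(series), 4L)
  expect_true(all(series$rmsd >= 0))
  expect_identical(series$time, traj$times)
})
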