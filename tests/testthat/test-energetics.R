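cfg <- energy_config()

test_that("Lennard-Jones energy matches closed forms", {
  # pair at the LJ minimum separation: energy is -epsilon
  pair <- atom_cloud(rbind(c(0, 0, 0), c(3.5 * 2^(1 / 6), 0, 0)),
                     lj_sigma = 3.5, lj_epsilon = 0.2)
  expect_equal(lj_energy(pair, cfg), -0.2, tolerance = 1e-12)
  # beyond the cutoff the interaction vanishes
  far <- atom_cloud(rbind(c(0, 0, 0), c(11, 0, 0)))
  expect_identical(lj_energy(far, energy_config(cutoff = 10)), 0)
  # zero distance is a hard error naming the pair
  clash <- atom_cloud(rbind(c(0, 0, 0), c(0, 0, 0)))
  expect_error(lj_energy(clash, cfg), "zero interatomic distance")
})

test_that("Coulomb energy matches closed forms", {
  pair <- atom_cloud(rbind(c(0, 0, 0), c(3.320636, 0, 0)),
                     charge = c(1, -1))
  expect_equal(coulomb_energy(pair, cfg), -100, tolerance = 1e-6)
  neutral <- atom_cloud(matrix(rnorm(15), 5, 3), charge = 0)
  expect_identical(coulomb_energy(neutral, cfg), 0)
})

test_that("pairwise energies equal the brute-force double loop", {
  set.seed(11)
  for (rep in 1:5) {
    n <- sample(10:30, 1)
    cl <- atom_cloud(matrix(rnorm(n * 3, sd = 4), n, 3),
                     lj_sigma = runif(n, 3, 4),
                     lj_epsilon = runif(n, 0.05, 0.3),
                     charge = runif(n, -1, 1))
    # effectively cutoff-less
    big <- energy_config(cutoff = 1e6)
    oracle <- brute_force_nb(cl, cutoff = Inf)
    expect_equal(lj_energy(cl, big), oracle$lj, tolerance = 1e-10)
    expect_equal(coulomb_energy(cl, big), oracle$coulomb, tolerance = 1e-10)
    # with a cutoff, equals brute force restricted to pairs <= cutoff
    oracle10 <- brute_force_nb(cl, cutoff = 10)
    expect_equal(lj_energy(cl, cfg), oracle10$lj, tolerance = 1e-10)
    expect_equal(coulomb_energy(cl, cfg), oracle10$coulomb, tolerance = 1e-10)
  }
})

test_that("bonded and same-residue pairs are excluded, 1-4 interact", {
  pep <- build_ideal_helix("AA")
  # independent reconstruction: BFS bond distances over the bond list
  n <- nrow(pep$atoms)
  adj <- lapply(seq_len(n), function(i) integer())
  for (k in seq_len(nrow(pep$bonds))) {
    a <- pep$bonds[k, 1]; b <- pep$bonds[k, 2]
    adj[[a]] <- c(adj[[a]], b); adj[[b]] <- c(adj[[b]], a)
  }
  bond_dist <- function(a, b) {
    seen <- setNames(rep(Inf, n), seq_len(n)); seen[a] <- 0
    frontier <- a
    for (d in 1:3) {
      frontier <- unique(unlist(adj[frontier]))
      frontier <- frontier[seen[frontier] == Inf]
      seen[frontier] <- d
      if (b %in% frontier) return(d)
    }
    seen[b]
  }
  at <- pep$atoms
  expected_lj <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (at$residue_index[i] == at$residue_index[j]) next
      if (bond_dist(i, j) < 3) next
      r <- sqrt(sum((unlist(at[i, c("x", "y", "z")]) -
                       unlist(at[j, c("x", "y", "z")]))^2))
      if (r > cfg$cutoff) next
      s <- (at$lj_sigma[i] + at$lj_sigma[j]) / 2
      e <- sqrt(at$lj_epsilon[i] * at$lj_epsilon[j])
      expected_lj <- expected_lj + 4 * e * ((s / r)^12 - (s / r)^6)
    }
  }
  expect_equal(lj_energy(pep, cfg), expected_lj, tolerance = 1e-10)
})

test_that("energies are invariant under rigid motions and atom reordering", {
  set.seed(7)
  n <- 12
  co <- matrix(rnorm(n * 3, sd = 3), n, 3)
  q <- runif(n, -0.5, 0.5)
  cl <- atom_cloud(co, charge = q, solvation_param = 0.02)
  e0 <- total_energy(cl, cfg)
  for (rep in 1:5) {
    R <- random_rotation()
    shift <- rnorm(3, sd = 8)
    cl2 <- atom_cloud(sweep(co %*% t(R), 2, -shift), charge = q,
                      solvation_param = 0.02)
    e2 <- total_energy(cl2, cfg)
    expect_equal(e2$lj, e0$lj, tolerance = 1e-8)
    expect_equal(e2$coulomb, e0$coulomb, tolerance = 1e-8)
    expect_equal(e2$solvation, e0$solvation, tolerance = 1e-8)
  }
  perm <- sample(n)
  cl3 <- atom_cloud(co[perm, ], charge = q[perm], solvation_param = 0.02)
  expect_equal(lj_energy(cl3, cfg), e0$lj, tolerance = 1e-10)
  expect_equal(coulomb_energy(cl3, cfg), e0$coulomb, tolerance = 1e-10)
})

test_that("SASA matches closed-form and grid oracles", {
  # isolated atom: full sphere of radius R + probe
  single <- atom_cloud(matrix(0, 1, 3), vdw_radius = 1.7)
  a <- sasa(single, probe_radius = 1.4, n_sphere_points = 960)
  expect_equal(attr(a, "total"), 4 * pi * 3.1^2, tolerance = 0.02)
  # atom enclosed in a tight octahedral cage is fully buried
  cage <- rbind(c(0, 0, 0),
                2.0 * rbind(diag(3), -diag(3)))
  caged <- atom_cloud(cage, vdw_radius = c(1.7, rep(2.5, 6)))
  expect_lt(sasa(caged, 1.4, 960)[1], 1)
  # two partially overlapping spheres vs fine-grid numerical integration
  d <- 2.5
  two <- atom_cloud(rbind(c(0, 0, 0), c(d, 0, 0)), vdw_radius = 1.7)
  est <- attr(sasa(two, 1.4, 960), "total")
  # grid oracle: spherical cap area by 1D integration over polar angle
  R <- 1.7 + 1.4
  # exposed fraction of each sphere: points with distance >= R from the
  # other center; cap angle from the lens geometry
  cos_theta <- d / (2 * R)
  exposed_one <- 2 * pi * R^2 * (1 + cos_theta)
  expect_equal(est, 2 * exposed_one, tolerance = 0.02 * 2 * exposed_one)
})

test_that("solvation energy is the SASA-weighted parameter sum and is monotone in burial", {
  zero <- atom_cloud(matrix(rnorm(12), 4, 3), solvation_param = 0)
  expect_identical(solvation_energy(zero), 0)
  single <- atom_cloud(matrix(0, 1, 3), vdw_radius = 1.65,
                       solvation_param = 0.012)
  expect_equal(solvation_energy(single),
               0.012 * 4 * pi * (1.65 + 1.4)^2, tolerance = 0.02 * 0.4)
  # burying an atom with positive solvation parameter lowers the term
  probe_sp <- c(0.03, 0, 0)
  exposed <- atom_cloud(rbind(c(0, 0, 0), c(8, 0, 0), c(12, 0, 0)),
                        solvation_param = probe_sp, vdw_radius = 1.9)
  buried <- atom_cloud(rbind(c(0, 0, 0), c(2.2, 0, 0), c(-2.2, 0, 0)),
                       solvation_param = probe_sp, vdw_radius = 1.9)
  expect_lt(solvation_energy(buried), solvation_energy(exposed))
  # unknown backend is rejected listing registered ones
  bad <- solvation_config(model = "pbl")
  expect_error(solvation_energy(single, bad), "sasa")
})

test_that("total energy is exactly the sum of its three terms and is reproducible", {
  pep <- build_ideal_helix("MATLE")
  e <- total_energy(pep, cfg)
  expect_identical(e$total, e$lj + e$coulomb + e$solvation)
  expect_equal(e$lj, lj_energy(pep, cfg))
  expect_equal(e$coulomb, coulomb_energy(pep, cfg))
  e2 <- total_energy(build_ideal_helix("MATLE"), cfg)
  expect_identical(e$total, e2$total)
  # neutral nonpolar toy: total is the LJ term alone
  toy <- atom_cloud(rbind(c(0, 0, 0), c(4, 0, 0)))
  et <- total_energy(toy, cfg)
  expect_identical(et$total, et$lj)
})

test_that("delta_e follows the mutant-minus-native sign convention", {
  expect_identical(delta_e(-500, -480), -20)
  expect_identical(delta_e(-480, -480), 0)
  e <- structure(list(total = -10), class = "energy_breakdown")
  e0 <- structure(list(total = -12), class = "energy_breakdown")
  expect_identical(delta_e(e, e0), 2)
})

test_that("steepest descent finds the LJ minimum and never increases the total", {
  # already-minimal pair: no accepted steps
  minpair <- atom_cloud(rbind(c(0, 0, 0), c(3.5 * 2^(1 / 6), 0, 0)))
  out <- minimize(minpair, cfg, max_steps = 100, force_tol = 1e-3)
  lg <- attr(out, "minimize_log")
  expect_equal(nrow(lg), 1)
  expect_identical(out$atoms[, c("x", "y", "z")],
                   minpair$atoms[, c("x", "y", "z")])
  # compressed pair relaxes to the known minimum separation
  squeezed <- atom_cloud(rbind(c(0, 0, 0), c(0.9 * 3.5, 0, 0)))
  rel <- minimize(squeezed, cfg, max_steps = 5000, force_tol = 1e-6,
                  backbone_fixed = FALSE)
  r <- sqrt(sum((unlist(rel$atoms[1, c("x", "y", "z")]) -
                   unlist(rel$atoms[2, c("x", "y", "z")]))^2))
  expect_equal(r, 3.5 * 2^(1 / 6), tolerance = 1e-3 / (3.5 * 2^(1 / 6)))
  # monotonicity audit on a mutated helix
  pep <- apply_mutation(build_ideal_helix(htt_nterm_sequence()), "A10W")
  out2 <- minimize(pep, cfg, max_steps = 60)
  lg2 <- attr(out2, "minimize_log")
  expect_true(all(diff(lg2$total) <= 0))
  expect_lte(lg2$total[nrow(lg2)], lg2$total[1])
  # backbone stays put under backbone_fixed
  bb <- backbone <- pep$atoms$name %in% c("N", "CA", "C", "O")
  expect_identical(out2$atoms[bb, c("x", "y", "z")],
                   pep$atoms[bb, c("x", "y", "z")])
})

test_that("severe steric overlap is rejected at minimization start", {
  clash <- atom_cloud(rbind(c(0, 0, 0), c(1e-4, 0, 0)))
  expect_error(minimize(clash, cfg), "clash too severe")
})
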