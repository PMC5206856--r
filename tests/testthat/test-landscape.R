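test_that("a small scan has the right shape, zero identity cells, and order independence", {
  pep <- build_ideal_helix("MAT")
  cfg <- energy_config()
  tab <- scan_single_point(pep, cfg, max_steps = 40)
  expect_identical(dim(tab$values), c(3L, 20L))
  expect_identical(colnames(tab$values), canonical_residues())
  for (p in 1:3) expect_identical(tab$values[p, pep$sequence[p]], 0)
  expect_false(anyNA(tab$values))
  # scanning positions in reverse yields a bit-identical table
  tab_rev <- scan_single_point(pep, cfg, max_steps = 40, positions = 3:1)
  expect_identical(tab$values, tab_rev$values)
})

test_that("scan cells equal an independent one-off mutant evaluation", {
  pep <- build_ideal_helix("MAT")
  cfg <- energy_config()
  tab <- scan_single_point(pep, cfg, max_steps = 40)
  # independent recomputation outside the scan loop
  native_rel <- minimize(pep, cfg, max_steps = 40, backbone_fixed = TRUE)
  e0 <- total_energy(native_rel, cfg)$total
  mut <- apply_mutation(native_rel, "A2K")
  mut_rel <- minimize(mut, cfg, max_steps = 40, backbone_fixed = TRUE)
  expect_equal(tab$values[2, "K"],
               total_energy(mut_rel, cfg)$total - e0, tolerance = 1e-12)
})

test_that("combination estimates are table sums with strict validation", {
  tab <- toy_table("MKT", seed = 1)
  est <- estimate_combination(tab, "M1A")
  expect_identical(est$delta_e_estimate, tab$values[1, "A"])
  expect_identical(estimate_combination(tab, "")$delta_e_estimate, 0)
  two <- estimate_combination(tab, "M1A K2R")
  expect_identical(two$delta_e_estimate,
                   tab$values[1, "A"] + tab$values[2, "R"])
  expect_error(estimate_combination(tab, "M1A M1C"), "duplicate positions")
  expect_error(estimate_combination(tab, "K1A"), "wild-type mismatch")
})

test_that("additive estimates are exactly additive over disjoint sets", {
  set.seed(21)
  tab <- toy_table("MKTLE")
  for (rep in 1:10) {
    posA <- sample(5, 2)
    posB <- setdiff(sample(5, 4), posA)[1:2]
    mk <- function(ps) {
      paste0(tab$native_sequence[ps], ps,
             vapply(ps, function(p) sample(setdiff(canonical_residues(),
                                                   tab$native_sequence[p]), 1),
                    character(1)), collapse = " ")
    }
    a <- mk(posA); b <- mk(posB)
    # additivity is exact in exact arithmetic; allow one ulp of float
    # reassociation between the two summation orders
    expect_equal(estimate_combination(tab, paste(a, b))$delta_e_estimate,
                 estimate_combination(tab, a)$delta_e_estimate +
                   estimate_combination(tab, b)$delta_e_estimate,
                 tolerance = 1e-14)
  }
})

test_that("top-k enumeration equals the exhaustive oracle, including ties", {
  set.seed(5)
  for (rep in 1:4) {
    tab <- toy_table("MKTLE")
    top <- enumerate_top_k(tab, n = 2, k = 10)
    oracle <- brute_force_topk(tab, n = 2, k = 10)
    expect_identical(top$mutations, oracle$mutations)
    expect_equal(top$delta_e_estimate, oracle$value)
  }
  # deliberately tied values exercise the lexicographic tie-break
  vals <- matrix(0, 2, 20, dimnames = list(NULL, canonical_residues()))
  vals[1, ] <- -1
  vals[2, ] <- -1
  tab_tie <- toy_table("AC", values = vals)
  top_tie <- enumerate_top_k(tab_tie, n = 2, k = 8)
  oracle_tie <- brute_force_topk(tab_tie, n = 2, k = 8)
  expect_identical(top_tie$mutations, oracle_tie$mutations)
  # n = 1, k = 1 is the global minimum cell
  tab1 <- toy_table("MKT", seed = 9)
  best <- enumerate_top_k(tab1, 1, 1)
  expect_equal(best$delta_e_estimate, min(tab1$values))
})

test_that("top-k respects the allowed set and position bounds", {
  tab <- toy_table("MKT", seed = 3)
  allowed <- "M1A M1C K2R"
  top <- enumerate_top_k(tab, n = 2, k = 5, allowed = allowed)
  expect_true(all(grepl("K2R", top$mutations)))
  expect_lte(nrow(top), 2)  # only 2 x 1 candidate products
  expect_error(enumerate_top_k(tab, n = 4, k = 1), "exceeds")
})

test_that("classification follows the sign rule with neutral identities", {
  vals <- matrix(0, 1, 20, dimnames = list(NULL, canonical_residues()))
  vals[1, "D"] <- -668.3
  vals[1, "K"] <- 12
  vals[1, "C"] <- 0
  tab <- toy_table("A", values = vals)
  lab <- classify_landscape(tab)
  expect_identical(unname(lab[1, "D"]), "stabilizing")
  expect_identical(unname(lab[1, "K"]), "destabilizing")
  expect_identical(unname(lab[1, "C"]), "neutral")
  expect_identical(unname(lab[1, "A"]), "neutral")
  counts <- table(factor(lab, levels = c("stabilizing", "destabilizing",
                                         "neutral")))
  expect_identical(sum(counts), 20L)
  # threshold widens the neutral band
  lab2 <- classify_landscape(tab, threshold = 20)
  expect_identical(unname(lab2[1, "K"]), "neutral")
})

test_that("landscape CSV round-trips values, sequence and provenance", {
  tab <- toy_table("MKT", seed = 2)
  f <- withr::local_tempfile(fileext = ".csv")
  write_delta_e_table(tab, f)
  back <- read_delta_e_table(f)
  expect_identical(back$native_sequence, tab$native_sequence)
  expect_equal(back$values, tab$values, ignore_attr = TRUE)
  expect_identical(back$provenance, "toy")
})

test_that("additive 2-point estimate matches direct recomputation for distant mutations", {
  pep <- build_ideal_helix(htt_nterm_sequence())
  cfg <- energy_config()
  native_rel <- minimize(pep, cfg, max_steps = 80, backbone_fixed = TRUE)
  e0 <- total_energy(native_rel, cfg)$total
  de_direct <- function(muts) {
    m <- apply_mutation(native_rel, muts)
    total_energy(minimize(m, cfg, max_steps = 80), cfg)$total - e0
  }
  # positions 2 and 16 are ~21 A apart on the helix (> 10 A cutoff)
  d1 <- de_direct("A2K")
  d2 <- de_direct("S16K")
  d12 <- de_direct("A2K S16K")
  gap <- abs(d12 - (d1 + d2))
  expect_lte(gap, max(2, 0.1 * abs(d12)))
})
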