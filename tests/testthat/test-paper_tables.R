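test_that("the embedded ranked-mutant table matches its printed structure", {
  t1 <- table1()
  expect_identical(nrow(t1), 20L)
  expect_identical(t1$id[1], "M1")
  expect_identical(t1$mutations[1], "L4K E5K K15D")
  expect_identical(t1$delta_e_estimate[1], -668.3)
  for (r in seq_len(20)) {
    m <- parse_mutations(t1$mutations[r])
    expect_identical(nrow(m), 3L)
    expect_false(anyDuplicated(m$position) > 0)
    # wild types agree with the native 17-mer
    expect_identical(m$wild_type,
                     strsplit(htt_nterm_sequence(), "")[[1]][m$position])
  }
  expect_identical(unname(table2_charges()["Native"]), 1L)
  expect_identical(length(table2_charges()), 21L)
})

test_that("full least-squares fit recovers single-point values with tiny residuals", {
  fit <- fit_single_point()
  expect_identical(fit$design_rank, 9L)
  expect_identical(sort(names(fit$parameters)),
                   sort(c("A2R", "T3K", "L4K", "E5K", "E12K", "K15D",
                          "K15E", "F17D", "F17E")))
  expect_lte(max(abs(fit$residuals)), 0.3)
  # independent normal-equations oracle built from scratch
  t1 <- table1()
  params <- sort(names(fit$parameters))
  X <- t(vapply(t1$mutations, function(s) {
    m <- parse_mutations(s)
    as.numeric(params %in% paste0(m$wild_type, m$position, m$mutant))
  }, numeric(9)))
  beta <- solve(t(X) %*% X, t(X) %*% t1$delta_e_estimate)
  expect_equal(unname(fit$parameters[params]), as.vector(beta),
               tolerance = 1e-8)
})

test_that("leave-one-out predictions reproduce the printed sums", {
  t1 <- table1()
  # M8 is the identifiability anchor; every other row is predictable
  for (r in which(t1$id != "M8")) {
    fit <- fit_single_point(exclude_ids = t1$id[r])
    pred <- fit$predict(t1$mutations[r])
    expect_equal(pred, t1$delta_e_estimate[r], tolerance = 0.5,
                 label = paste("LOO prediction for", t1$id[r]))
  }
})

test_that("excluding the anchor row is rejected as rank-deficient", {
  err <- expect_error(fit_single_point(exclude_ids = "M8"),
                      "rank-deficient")
  # the null direction spans all nine parameters (position-15 vs rest)
  expect_match(conditionMessage(err), "K15D")
  expect_match(conditionMessage(err), "K15E")
  expect_error(fit_single_point(exclude_ids = "M99"), "unknown row id")
})

test_that("refitting without the top row still ranks its combination first", {
  fit <- fit_single_point(exclude_ids = "M1")
  params <- names(fit$parameters)
  pos <- as.integer(gsub("[A-Z]", "", params))
  best <- Inf
  best_set <- NULL
  for (idx in utils::combn(length(params), 3, simplify = FALSE)) {
    if (length(unique(pos[idx])) < 3) next
    s <- sum(fit$parameters[idx])
    if (s < best) {
      best <- s
      best_set <- params[idx]
    }
  }
  expect_setequal(best_set, c("L4K", "E5K", "K15D"))
  expect_equal(best, -668.3, tolerance = 0.5)
})

test_that("exchange identities implied by additivity hold on the printed values", {
  cons <- additivity_consistency()
  find_gap <- function(a, b, c, d) {
    hit <- cons[(cons$identity == paste0(a, "-", b, " = ", c, "-", d)) |
                  (cons$identity == paste0(c, "-", d, " = ", a, "-", b)) |
                  (cons$identity == paste0(b, "-", a, " = ", d, "-", c)) |
                  (cons$identity == paste0(d, "-", c, " = ", b, "-", a)), ]
    expect_gte(nrow(hit), 1)
    hit$gap[1]
  }
  expect_lte(find_gap("M1", "M4", "M6", "M16"), 0.2)
  expect_lte(find_gap("M11", "M14", "M12", "M17"), 0.2)
  # duplicated rows give exactly matching differences
  dup <- table1()[c(1, 2, 1, 2), ]
  dup$id <- c("A", "B", "C", "D")
  cons2 <- additivity_consistency(dup)
  expect_true(any(cons2$gap == 0))
})

test_that("mutant sequences honour the printed dash notation", {
  expect_identical(mutant_sequence("L4K E12K K15E"), "MATKEKLMKAFKSLESF")
  expect_identical(mutant_sequence("A2R T3K K15D"), "MRKLEKLMKAFESLDSF")
  expect_error(mutant_sequence("K4L"), "wild-type mismatch")
})
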