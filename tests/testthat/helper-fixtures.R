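# Shared fixtures and independent oracles for the test suite.

# A random rotation matrix from a fixed stream.
random_rotation <- function() {
  th <- runif(1, 0, 2 * pi)
  ax <- rnorm(3)
  ax <- ax / sqrt(sum(ax^2))
  K <- matrix(c(0, -ax[3], ax[2],
                ax[3], 0, -ax[1],
                -ax[2], ax[1], 0), 3, 3, byrow = TRUE)
  diag(3) + sin(th) * K + (1 - cos(th)) * K %*% K
}

# Brute-force double-loop LJ + Coulomb oracle over a toy atom cloud.
brute_force_nb <- function(cloud, cutoff = Inf, k = 332.0636, eps_r = 1) {
  at <- cloud$atoms
  n <- nrow(at)
  lj <- 0
  coul <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      r <- sqrt((at$x[i] - at$x[j])^2 + (at$y[i] - at$y[j])^2 +
                  (at$z[i] - at$z[j])^2)
      if (r > cutoff) next
      s <- (at$lj_sigma[i] + at$lj_sigma[j]) / 2
      e <- sqrt(at$lj_epsilon[i] * at$lj_epsilon[j])
      lj <- lj + 4 * e * ((s / r)^12 - (s / r)^6)
      coul <- coul + k * at$charge[i] * at$charge[j] / (eps_r * r)
    }
  }
  list(lj = lj, coulomb = coul)
}

# Exhaustive top-k oracle over a delta_e_table: enumerate every n-subset
# of positions times every residue assignment.
brute_force_topk <- function(table, n, k) {
  npos <- length(table$native_sequence)
  aas <- canonical_residues()
  rows <- list()
  for (posset in utils::combn(npos, n, simplify = FALSE)) {
    cand <- lapply(posset, function(p) setdiff(aas, table$native_sequence[p]))
    grid <- do.call(expand.grid, c(cand, stringsAsFactors = FALSE))
    for (g in seq_len(nrow(grid))) {
      res <- unlist(grid[g, ], use.names = FALSE)
      val <- sum(vapply(seq_len(n),
                        function(s) table$values[posset[s], res[s]],
                        numeric(1)))
      key <- paste(sprintf("%03d%s", posset, res), collapse = "")
      mut <- paste0(table$native_sequence[posset], posset, res,
                    collapse = " ")
      rows[[length(rows) + 1L]] <- data.frame(mutations = mut, value = val,
                                              key = key,
                                              stringsAsFactors = FALSE)
    }
  }
  df <- do.call(rbind, rows)
  df <- df[order(df$value, df$key), ]
  head(df, k)
}

# Independent quaternion-based optimal superposition RMSD oracle
# (Horn 1987 closed form), structurally unrelated to the SVD route.
quaternion_rmsd <- function(mobile, reference) {
  m0 <- sweep(mobile, 2, colMeans(mobile))
  r0 <- sweep(reference, 2, colMeans(reference))
  S <- crossprod(m0, r0)
  K <- matrix(0, 4, 4)
  K[1, 1] <- S[1, 1] + S[2, 2] + S[3, 3]
  K[1, 2] <- K[2, 1] <- S[2, 3] - S[3, 2]
  K[1, 3] <- K[3, 1] <- S[3, 1] - S[1, 3]
  K[1, 4] <- K[4, 1] <- S[1, 2] - S[2, 1]
  K[2, 2] <- S[1, 1] - S[2, 2] - S[3, 3]
  K[2, 3] <- K[3, 2] <- S[1, 2] + S[2, 1]
  K[2, 4] <- K[4, 2] <- S[1, 3] + S[3, 1]
  K[3, 3] <- -S[1, 1] + S[2, 2] - S[3, 3]
  K[3, 4] <- K[4, 3] <- S[2, 3] + S[3, 2]
  K[4, 4] <- -S[1, 1] - S[2, 2] + S[3, 3]
  lam <- max(eigen(K, symmetric = TRUE)$values)
  msd <- (sum(m0^2) + sum(r0^2) - 2 * lam) / nrow(mobile)
  sqrt(max(0, msd))
}

# Small synthetic landscape with hand-set values for enumeration tests.
toy_table <- function(native = "MKT", values = NULL, seed = NULL) {
  native <- strsplit(native, "")[[1]]
  aas <- canonical_residues()
  if (is.null(values)) {
    if (!is.null(seed)) set.seed(seed)
    values <- matrix(round(rnorm(length(native) * 20, sd = 5), 1),
                     nrow = length(native), ncol = 20,
                     dimnames = list(NULL, aas))
  }
  for (p in seq_along(native)) values[p, native[p]] <- 0
  delta_e_table(values, native, provenance = "toy")
}
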