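# Single-point mutational energy landscape and additive multi-point
# estimates.

#' Construct a delta-E landscape table
#'
#' A positions x 20 matrix of stability changes (mutant minus native
#' total energy, kcal/mol) with the native sequence and a provenance
#' string recording the energy configuration that produced it. Identity
#' cells (the native residue at each position) are exactly zero.
#'
#' @param values Numeric matrix, positions x 20; column names must be the
#'   canonical residue letters.
#' @param native_sequence Sequence the landscape refers to.
#' @param provenance Configuration provenance string.
#' @return A `delta_e_table`.
#' @export
delta_e_table <- function(values, native_sequence, provenance = "") {
  native_sequence <- as_residue_vector(native_sequence)
  stopifnot(is.matrix(values),
            nrow(values) == length(native_sequence),
            identical(colnames(values), canonical_residues()))
  for (p in seq_along(native_sequence)) {
    if (values[p, native_sequence[p]] != 0) {
      stop("identity cell at position ", p, " must be 0", call. = FALSE)
    }
  }
  rownames(values) <- as.character(seq_along(native_sequence))
  structure(list(values = values, native_sequence = native_sequence,
                 provenance = provenance),
            class = "delta_e_table")
}

#' @export
print.delta_e_table <- function(x, ...) {
  cat("<delta_e_table> ", paste(x$native_sequence, collapse = ""), "\n",
      "  ", nrow(x$values), " positions x 20 residues; provenance: ",
      x$provenance, "\n", sep = "")
  invisible(x)
}

#' Exhaustive single-point mutational scan
#'
#' Relaxes the native structure once (side chains only) to obtain the
#' reference energy E0, then for every (position, alternative residue)
#' pair applies the mutation on the fixed backbone, relaxes the side
#' chains, and records `delta_e = E - E0`. Identity cells are zero by
#' construction. The scan is deterministic and order-independent.
#'
#' @param pep The native [peptide()] (typically [build_ideal_helix()] of
#'   the native sequence).
#' @param config An [energy_config()].
#' @param max_steps Per-structure relaxation step cap (default 200).
#' @param positions Positions to scan (default all); other rows are kept
#'   at zero only for the identity cell and `NA` elsewhere.
#' @return A [delta_e_table()].
#' @export
scan_single_point <- function(pep, config = energy_config(),
                              max_steps = 200,
                              positions = seq_along(pep$sequence)) {
  aas <- canonical_residues()
  native_relaxed <- minimize(pep, config, max_steps = max_steps,
                             backbone_fixed = TRUE)
  e0 <- total_energy(native_relaxed, config)$total
  values <- matrix(NA_real_, nrow = length(pep$sequence), ncol = length(aas),
                   dimnames = list(as.character(seq_along(pep$sequence)), aas))
  for (p in seq_along(pep$sequence)) values[p, pep$sequence[p]] <- 0
  for (p in positions) {
    native_res <- pep$sequence[p]
    for (aa in setdiff(aas, native_res)) {
      val <- tryCatch({
        mut <- .apply_one_mutation(native_relaxed, p, native_res, aa)
        rel <- minimize(mut, config, max_steps = max_steps,
                        backbone_fixed = TRUE)
        total_energy(rel, config)$total - e0
      }, error = function(e) {
        stop("scan failed at (position ", p, ", residue ", aa, "): ",
             conditionMessage(e), call. = FALSE)
      })
      values[p, aa] <- val
    }
  }
  delta_e_table(values, pep$sequence, config_provenance(config))
}

# Validate a mutation set against a table: distinct positions, matching
# wild types.
.check_combo <- function(table, muts) {
  if (anyDuplicated(muts$position)) {
    stop("duplicate positions in mutation combination: ",
         format_mutations(muts), call. = FALSE)
  }
  for (k in seq_len(nrow(muts))) {
    p <- muts$position[k]
    if (p < 1 || p > length(table$native_sequence)) {
      stop("position ", p, " outside landscape", call. = FALSE)
    }
    if (table$native_sequence[p] != muts$wild_type[k]) {
      stop("wild-type mismatch at position ", p, ": expected ",
           table$native_sequence[p], ", found ", muts$wild_type[k],
           call. = FALSE)
    }
  }
  invisible(muts)
}

#' Additive estimate for a multi-point mutation
#'
#' Estimates the stability change of an n-point mutant as the sum of the
#' constituent single-point landscape entries, without re-evaluating any
#' structure energy. Positions must be pairwise distinct and wild types
#' must match the landscape's native sequence.
#'
#' @param table A [delta_e_table()].
#' @param mutations Mutation set: a string like `"L4K E12K K15E"` or a
#'   data.frame from [parse_mutations()]. An empty set estimates 0.
#' @return A `combination_estimate` list: `mutations`, `delta_e_estimate`
#'   and (unset) `rank`.
#' @export
estimate_combination <- function(table, mutations) {
  muts <- as_mutation_frame(mutations)
  .check_combo(table, muts)
  est <- 0
  for (k in seq_len(nrow(muts))) {
    est <- est + table$values[muts$position[k], muts$mutant[k]]
  }
  structure(list(mutations = muts, delta_e_estimate = est, rank = NA_integer_),
            class = "combination_estimate")
}

# deterministic lexicographic tie key for a mutation set
.combo_key <- function(positions, residues) {
  o <- order(positions)
  paste(sprintf("%03d%s", positions[o], residues[o]), collapse = "")
}

#' Enumerate the k best n-point combinations
#'
#' Returns the `k` combinations of `n` mutations at pairwise-distinct
#' positions with the lowest additive estimates, in ascending order, via
#' best-first expansion over per-position sorted candidate lists. The
#' result equals exhaustive enumeration, with ties broken by
#' lexicographic (position, residue) order.
#'
#' @param table A [delta_e_table()].
#' @param n Number of simultaneous mutations (>= 1).
#' @param k Number of combinations to return (>= 1).
#' @param allowed Optional restriction: a mutation set (string or
#'   data.frame) from which candidates are drawn.
#' @return data.frame with columns `rank`, `mutations` (string notation)
#'   and `delta_e_estimate`, ascending.
#' @export
enumerate_top_k <- function(table, n, k, allowed = NULL) {
  stopifnot(n >= 1, k >= 1)
  aas <- canonical_residues()
  npos <- length(table$native_sequence)
  allowed_df <- if (!is.null(allowed)) as_mutation_frame(allowed) else NULL
  cand <- vector("list", npos)
  for (p in seq_len(npos)) {
    res <- setdiff(aas, table$native_sequence[p])
    if (!is.null(allowed_df)) {
      res <- intersect(res, allowed_df$mutant[allowed_df$position == p])
    }
    res <- res[!is.na(table$values[p, res])]
    if (length(res) == 0) next
    v <- table$values[p, res]
    o <- order(v, res)
    cand[[p]] <- list(res = res[o], val = unname(v[o]))
  }
  valid <- which(!vapply(cand, is.null, logical(1)))
  if (n > length(valid)) {
    stop("n = ", n, " exceeds the ", length(valid),
         " positions with candidate mutations", call. = FALSE)
  }
  combos <- combn(valid, n)
  # best-first search over states (combo, per-slot candidate indices);
  # successors increment slots >= `last` to enumerate each index vector once
  st_val <- numeric(0)
  st <- list()
  push <- function(combo_col, idx, last) {
    pos <- combos[, combo_col]
    v <- sum(vapply(seq_len(n), function(s) cand[[pos[s]]]$val[idx[s]],
                    numeric(1)))
    st[[length(st) + 1L]] <<- list(cc = combo_col, idx = idx, last = last)
    st_val[length(st_val) + 1L] <<- v
  }
  for (cc in seq_len(ncol(combos))) push(cc, rep(1L, n), 1L)
  out_val <- numeric(0)
  out_pos <- list()
  out_res <- list()
  kth <- Inf
  while (length(st_val) > 0) {
    b <- which.min(st_val)
    v <- st_val[b]
    if (length(out_val) >= k && v > kth + 1e-9) break
    s <- st[[b]]
    st <- st[-b]
    st_val <- st_val[-b]
    pos <- combos[, s$cc]
    out_val[length(out_val) + 1L] <- v
    out_pos[[length(out_pos) + 1L]] <- pos
    out_res[[length(out_res) + 1L]] <-
      vapply(seq_len(n), function(sl) cand[[pos[sl]]]$res[s$idx[sl]],
             character(1))
    if (length(out_val) == k) kth <- sort(out_val)[k]
    for (sl in s$last:n) {
      idx2 <- s$idx
      idx2[sl] <- idx2[sl] + 1L
      if (idx2[sl] <= length(cand[[pos[sl]]]$res)) push(s$cc, idx2, sl)
    }
  }
  keys <- vapply(seq_along(out_val),
                 function(m) .combo_key(out_pos[[m]], out_res[[m]]),
                 character(1))
  o <- order(out_val, keys)[seq_len(min(k, length(out_val)))]
  mut_strings <- vapply(o, function(m) {
    pos <- out_pos[[m]]
    res <- out_res[[m]]
    ord <- order(pos)
    paste0(table$native_sequence[pos[ord]], pos[ord], res[ord],
           collapse = " ")
  }, character(1))
  data.frame(rank = seq_along(o), mutations = mut_strings,
             delta_e_estimate = out_val[o], stringsAsFactors = FALSE)
}

#' Classify landscape cells by the sign of delta-E
#'
#' Cells below `-threshold` are `stabilizing`, above `+threshold`
#' `destabilizing`, otherwise `neutral`; identity cells are always
#' neutral.
#'
#' @param table A [delta_e_table()].
#' @param threshold Non-negative margin in kcal/mol (default 0).
#' @return Character matrix of labels with the table's dimensions.
#' @export
classify_landscape <- function(table, threshold = 0) {
  stopifnot(threshold >= 0)
  v <- table$values
  lab <- matrix("neutral", nrow(v), ncol(v), dimnames = dimnames(v))
  lab[!is.na(v) & v < -threshold] <- "stabilizing"
  lab[!is.na(v) & v > threshold] <- "destabilizing"
  for (p in seq_along(table$native_sequence)) {
    lab[p, table$native_sequence[p]] <- "neutral"
  }
  lab
}

#' Write / read a landscape table as CSV
#'
#' Rows are positions 1..N with the native residue; the 20 residue
#' columns hold delta-E values. The provenance string is stored in a
#' leading `#` comment line.
#'
#' @param table A [delta_e_table()].
#' @param path Output file.
#' @export
write_delta_e_table <- function(table, path) {
  df <- data.frame(position = seq_along(table$native_sequence),
                   native = table$native_sequence,
                   table$values, check.names = FALSE,
                   stringsAsFactors = FALSE)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# provenance: ", table$provenance), con)
  write.table(df, con, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_delta_e_table
#' @return `read_delta_e_table` returns the [delta_e_table()].
#' @export
read_delta_e_table <- function(path) {
  first <- readLines(path, n = 1)
  prov <- if (startsWith(first, "# provenance: ")) {
    sub("^# provenance: ", "", first)
  } else ""
  df <- read.table(path, sep = ",", header = TRUE, comment.char = "#",
                   check.names = FALSE, stringsAsFactors = FALSE)
  values <- as.matrix(df[, canonical_residues()])
  delta_e_table(values, df$native, provenance = prov)
}

#' Write ranked combinations as TSV
#'
#' Columns mirror the ranked-mutant table layout: id, mutation string and
#' additive estimate.
#'
#' @param ranked data.frame from [enumerate_top_k()].
#' @param path Output file.
#' @export
write_combinations <- function(ranked, path) {
  df <- data.frame(id = paste0("M", ranked$rank),
                   mutations = ranked$mutations,
                   delta_e_estimate = ranked$delta_e_estimate,
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
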