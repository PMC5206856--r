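# Three-criteria candidate selection: stability rank, hydrophobic-to-
# charged replacement, and breaking of the oligomerization contact at
# positions 6/15.

#' Selection criteria
#'
#' Defaults: the hydrophobic set is the ALIPHATIC residues
#' `{A, V, I, L, M}` (aromatic F/W/Y are deliberately excluded; see the
#' methods vignette), the charged set is `{D, E, K, R}`, and the
#' oligomer-contact positions are 6 and 15 (the lysines believed to form
#' the solvent-inaccessible intermolecular side-chain interaction).
#'
#' @param hydrophobic_set Residues counted as hydrophobic wild types.
#' @param charged_set Residues counted as charged replacements.
#' @param contact_positions Positions whose substitution breaks the
#'   intermolecular contact.
#' @param stability_max_rank Maximum stability rank admitted (default
#'   `Inf`: membership in the ranked input suffices).
#' @return A `selection_criteria` object.
#' @export
selection_criteria <- function(hydrophobic_set = c("A", "V", "I", "L", "M"),
                               charged_set = c("D", "E", "K", "R"),
                               contact_positions = c(6L, 15L),
                               stability_max_rank = Inf) {
  hydrophobic_set <- as_residue_vector(hydrophobic_set)
  charged_set <- as_residue_vector(charged_set)
  stopifnot(all(contact_positions >= 1))
  structure(list(hydrophobic_set = hydrophobic_set,
                 charged_set = charged_set,
                 contact_positions = as.integer(contact_positions),
                 stability_max_rank = stability_max_rank),
            class = "selection_criteria")
}

#' Hydrophobic-to-charged replacement flag
#'
#' `TRUE` iff at least one mutation in the combination replaces a
#' hydrophobic wild-type residue with a charged one.
#'
#' @param combo Mutation set (string like `"L4K E12K K15E"` or parsed
#'   data.frame).
#' @param criteria A [selection_criteria()].
#' @return Logical flag.
#' @export
hydrophobic_to_charged <- function(combo, criteria = selection_criteria()) {
  muts <- as_mutation_frame(combo)
  any(muts$wild_type %in% criteria$hydrophobic_set &
        muts$mutant %in% criteria$charged_set)
}

#' Oligomer-contact breaking flag
#'
#' `TRUE` iff some mutation in the combination falls on one of the
#' contact positions (default 6 or 15).
#'
#' @inheritParams hydrophobic_to_charged
#' @return Logical flag.
#' @export
breaks_oligomer_contact <- function(combo, criteria = selection_criteria()) {
  muts <- as_mutation_frame(combo)
  any(muts$position %in% criteria$contact_positions)
}

#' Apply the three selection criteria to ranked combinations
#'
#' Takes combinations ranked ascending by additive stability estimate and
#' reports, per combination, the stability rank, both boolean criteria
#' flags and the conjunction `passes_all`. Ordering is preserved.
#'
#' @param estimates data.frame with columns `mutations` (string notation)
#'   and `delta_e_estimate`, ranked ascending (e.g. from
#'   [enumerate_top_k()] or [table1()]); an optional `id` column is
#'   carried through.
#' @param criteria A [selection_criteria()].
#' @return data.frame with columns id, mutations, delta_e_estimate,
#'   stability_rank, flag_stability, flag_hydrophobic_replacement,
#'   flag_contact_break, passes_all.
#' @export
select_candidates <- function(estimates, criteria = selection_criteria()) {
  n <- nrow(estimates)
  ids <- if ("id" %in% names(estimates)) {
    estimates$id
  } else if (n == 0) {
    character(0)
  } else {
    paste0("M", seq_len(n))
  }
  rank <- seq_len(n)
  f_st <- rank <= criteria$stability_max_rank
  f_hc <- vapply(estimates$mutations, hydrophobic_to_charged,
                 logical(1), criteria = criteria, USE.NAMES = FALSE)
  f_cb <- vapply(estimates$mutations, breaks_oligomer_contact,
                 logical(1), criteria = criteria, USE.NAMES = FALSE)
  data.frame(id = ids, mutations = estimates$mutations,
             delta_e_estimate = estimates$delta_e_estimate,
             stability_rank = rank,
             flag_stability = f_st,
             flag_hydrophobic_replacement = f_hc,
             flag_contact_break = f_cb,
             passes_all = f_st & f_hc & f_cb,
             stringsAsFactors = FALSE)
}

#' Write a selection report as TSV
#'
#' @param report data.frame from [select_candidates()].
#' @param path Output file.
#' @export
write_selection_report <- function(report, path) {
  write.table(report, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
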