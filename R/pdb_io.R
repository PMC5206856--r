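# PDB exchange. File format handling is delegated to bio3d; on read, all
# force-field parameters are re-assigned from the embedded parameter
# table, and residues are renumbered 1..N (so fragments extracted with
# author numbering, e.g. 371-387, map onto the 1-based mutation
# notation).

#' Write a peptide as a PDB file
#'
#' Standard ATOM records (3-decimal coordinate precision, chain A).
#'
#' @param pep A [peptide()].
#' @param path Output file.
#' @export
write_pdb <- function(pep, path) {
  at <- pep$atoms
  bio3d::write.pdb(file = path,
                   xyz = as.vector(t(as.matrix(at[, c("x", "y", "z")]))),
                   resno = at$residue_index,
                   resid = aa_three_letter(pep$sequence[at$residue_index]),
                   eleno = seq_len(nrow(at)),
                   elety = at$name,
                   chain = rep("A", nrow(at)),
                   elesy = at$element)
  invisible(path)
}

#' Read a peptide from a PDB file
#'
#' Parses ATOM records, renumbers residues 1..N, and re-assigns partial
#' charges, LJ parameters, solvation parameters and van der Waals radii
#' from the embedded parameter table (PDB files carry none of these).
#' Residues missing any backbone atom are rejected by name; malformed
#' ATOM lines are rejected with their line number.
#'
#' @param path PDB file with ATOM records.
#' @return A [peptide()].
#' @export
read_pdb <- function(path) {
  lines <- readLines(path)
  is_atom <- startsWith(lines, "ATOM")
  if (!any(is_atom)) stop("no ATOM records in ", path, call. = FALSE)
  for (ln in which(is_atom)) {
    l <- lines[ln]
    coords_ok <- nchar(l) >= 54 &&
      !anyNA(suppressWarnings(as.numeric(c(substr(l, 31, 38),
                                           substr(l, 39, 46),
                                           substr(l, 47, 54)))))
    if (!coords_ok) {
      stop("unparseable ATOM line ", ln, " in ", path, call. = FALSE)
    }
  }
  pdb <- bio3d::read.pdb(path)
  at <- pdb$atom[pdb$atom$type == "ATOM", ]
  res_key <- paste(at$chain, at$resno, at$insert)
  res_index <- match(res_key, unique(res_key))
  sequence <- aa_one_letter(at$resid[!duplicated(res_index)])
  backbone <- vector("list", length(sequence))
  pos_list <- vector("list", length(sequence))
  for (i in seq_along(sequence)) {
    sub <- at[res_index == i, ]
    for (req in c("N", "CA", "C", "O")) {
      if (sum(sub$elety == req) != 1L) {
        stop("residue ", i, " is missing backbone atom ", req, call. = FALSE)
      }
    }
    pos_list[[i]] <- sub
    backbone[[i]] <- lapply(
      structure(c("N", "CA", "C", "O"), names = c("N", "CA", "C", "O")),
      function(nm) {
        r <- sub[sub$elety == nm, ]
        c(r$x, r$y, r$z)
      })
  }
  # assemble with template side chains, then overwrite any side-chain
  # coordinates that are present in the file
  pep <- .assemble_peptide(sequence, backbone)
  for (i in seq_along(sequence)) {
    sub <- pos_list[[i]]
    sel <- which(pep$atoms$residue_index == i)
    for (k in sel) {
      nm <- pep$atoms$name[k]
      row <- sub[sub$elety == nm, ]
      if (nrow(row) == 1) {
        pep$atoms[k, c("x", "y", "z")] <- c(row$x, row$y, row$z)
      }
    }
  }
  pep
}
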