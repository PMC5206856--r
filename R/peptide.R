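# Peptide representation and construction of idealized alpha-helical
# models on which all energy and mutation operations act.

# Natural-extension reference frame (NeRF) placement: given positions of
# reference atoms a-b-c, place d bonded to c at the stated bond length,
# angle b-c-d and dihedral a-b-c-d (degrees).
place_atom <- function(a, b, c, bond, angle, dihedral) {
  ang <- angle * pi / 180
  dih <- dihedral * pi / 180
  bc <- c - b
  bc <- bc / sqrt(sum(bc^2))
  ab <- b - a
  n <- c(ab[2] * bc[3] - ab[3] * bc[2],
         ab[3] * bc[1] - ab[1] * bc[3],
         ab[1] * bc[2] - ab[2] * bc[1])
  n <- n / sqrt(sum(n^2))
  m <- c(n[2] * bc[3] - n[3] * bc[2],
         n[3] * bc[1] - n[1] * bc[3],
         n[1] * bc[2] - n[2] * bc[1])
  d <- bond * c(-cos(ang), sin(ang) * cos(dih), sin(ang) * sin(dih))
  c + d[1] * bc + d[2] * m + d[3] * n
}

# Backbone geometry constants (A / degrees): standard peptide values.
.BB <- list(
  b_n_ca = 1.458, b_ca_c = 1.525, b_c_n = 1.329, b_c_o = 1.231,
  a_n_ca_c = 111.2, a_ca_c_n = 116.2, a_c_n_ca = 121.7, a_ca_c_o = 120.8,
  phi = -57, psi = -47, omega = 180
)

#' Construct a peptide object
#'
#' A peptide couples a one-letter sequence with a fully parameterized
#' heavy-atom model: coordinates, partial charges, Lennard-Jones
#' parameters, van der Waals radii and atomic solvation parameters, plus
#' the covalent bond list used for non-bonded exclusions. Invariants
#' enforced on construction: every atom belongs to a valid residue, every
#' residue carries exactly one N/CA/C/O backbone atom, and per-residue
#' partial charges sum to the residue's formal charge within 1e-6.
#'
#' @param sequence Character string or vector of one-letter codes.
#' @param atoms data.frame with columns name, class, element,
#'   residue_index, x, y, z, charge, lj_sigma, lj_epsilon,
#'   solvation_param, vdw_radius.
#' @param bonds Two-column integer matrix of atom-index bonds.
#' @return An object of class `peptide`.
#' @export
peptide <- function(sequence, atoms, bonds) {
  sequence <- as_residue_vector(sequence)
  n <- length(sequence)
  stopifnot(is.data.frame(atoms), is.matrix(bonds), ncol(bonds) == 2)
  if (any(atoms$residue_index < 1 | atoms$residue_index > n)) {
    stop("atom residue_index outside [1, ", n, "]", call. = FALSE)
  }
  coords <- as.matrix(atoms[, c("x", "y", "z")])
  if (!all(is.finite(coords))) stop("non-finite atom coordinates", call. = FALSE)
  if (any(atoms$lj_sigma <= 0) || any(atoms$lj_epsilon < 0) ||
      any(atoms$vdw_radius <= 0)) {
    stop("invalid LJ/vdW parameters", call. = FALSE)
  }
  for (i in seq_len(n)) {
    bb <- atoms$name[atoms$residue_index == i]
    for (req in c("N", "CA", "C", "O")) {
      if (sum(bb == req) != 1L) {
        stop("residue ", i, " must have exactly one backbone ", req,
             " atom", call. = FALSE)
      }
    }
    qsum <- sum(atoms$charge[atoms$residue_index == i])
    qref <- .FORMAL_CHARGE[[sequence[i]]]
    if (abs(qsum - qref) > 1e-6) {
      stop("residue ", i, " (", sequence[i], "): partial charges sum to ",
           format(qsum), ", expected ", qref, call. = FALSE)
    }
  }
  structure(list(sequence = sequence, atoms = atoms, bonds = bonds),
            class = "peptide")
}

#' @export
print.peptide <- function(x, ...) {
  cat("<peptide> ", paste(x$sequence, collapse = ""), "\n",
      "  ", length(x$sequence), " residues, ", nrow(x$atoms), " heavy atoms, ",
      nrow(x$bonds), " bonds\n", sep = "")
  invisible(x)
}

#' Get or replace peptide coordinates
#'
#' @param pep A [peptide()].
#' @return `peptide_coords` returns the `n_atoms x 3` coordinate matrix.
#' @export
peptide_coords <- function(pep) {
  as.matrix(pep$atoms[, c("x", "y", "z")])
}

#' @rdname peptide_coords
#' @param coords Replacement `n_atoms x 3` matrix.
#' @return `set_peptide_coords` returns the peptide with new coordinates.
#' @export
set_peptide_coords <- function(pep, coords) {
  pep$atoms$x <- coords[, 1]
  pep$atoms$y <- coords[, 2]
  pep$atoms$z <- coords[, 3]
  attr(pep, "nb_cache") <- NULL  # pair list survives, but keep it simple
  pep
}

# Indices of backbone atoms (N, CA, C, O).
backbone_indices <- function(pep) {
  which(pep$atoms$name %in% c("N", "CA", "C", "O"))
}

# Assemble the parameterized atom table + bonds for a sequence given
# backbone coordinates (list of per-residue named 3-vectors) and place
# side chains from the internal-coordinate templates.
.assemble_peptide <- function(sequence, backbone) {
  n <- length(sequence)
  rows <- vector("list", n)
  bonds <- list()
  offset <- 0L
  for (i in seq_len(n)) {
    res <- sequence[i]
    pos <- backbone[[i]]  # named list: N, CA, C, O coordinates
    tpl <- .SIDECHAIN_TEMPLATES[[res]]
    if (!is.null(tpl)) {
      for (k in seq_len(nrow(tpl))) {
        pos[[tpl$name[k]]] <- place_atom(pos[[tpl$a[k]]], pos[[tpl$b[k]]],
                                         pos[[tpl$c[k]]], tpl$bond[k],
                                         tpl$angle[k], tpl$dihedral[k])
      }
    }
    nm <- residue_atom_names(res)
    cls <- residue_atom_classes(res)[nm]
    ch <- residue_charges(res)[nm]
    par <- .ATOM_CLASSES[cls, ]
    xyz <- t(vapply(nm, function(a) pos[[a]], numeric(3)))
    rows[[i]] <- data.frame(
      name = nm, class = unname(cls), element = par$element,
      residue_index = i, x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
      charge = unname(ch), lj_sigma = par$sigma, lj_epsilon = par$epsilon,
      solvation_param = par$solv, vdw_radius = par$vdw,
      stringsAsFactors = FALSE, row.names = NULL
    )
    idx <- function(a) offset + match(a, nm)
    # backbone + side-chain parent-chain bonds
    b <- rbind(c(idx("N"), idx("CA")), c(idx("CA"), idx("C")),
               c(idx("C"), idx("O")))
    if (!is.null(tpl)) {
      b <- rbind(b, cbind(idx(tpl$c), idx(tpl$name)))
      rb <- .RING_BONDS[[res]]
      if (!is.null(rb)) b <- rbind(b, cbind(idx(rb[, 1]), idx(rb[, 2])))
    }
    if (i > 1L) {
      prev_c <- attr(rows[[i - 1L]], "c_index")
      b <- rbind(b, c(prev_c, idx("N")))
    }
    attr(rows[[i]], "c_index") <- idx("C")
    bonds[[i]] <- b
    offset <- offset + length(nm)
  }
  atoms <- do.call(rbind, rows)
  peptide(sequence, atoms, do.call(rbind, bonds))
}

#' Build an idealized alpha-helical peptide from sequence
#'
#' Generates heavy-atom coordinates for a canonical sequence with backbone
#' dihedrals phi = -57 deg, psi = -47 deg (ideal right-handed alpha
#' helix), standard bond lengths and angles, and side chains placed from
#' the embedded single-rotamer internal-coordinate templates. The output
#' is deterministic for a given sequence. All force-field parameters are
#' assigned from the embedded parameter table.
#'
#' @param sequence Character string (e.g. `"MATLEKLMKAFESLKSF"`) or vector
#'   of one-letter codes.
#' @return A [peptide()] object.
#' @examples
#' helix <- build_ideal_helix("MAT")
#' @export
build_ideal_helix <- function(sequence) {
  sequence <- as_residue_vector(sequence)
  n <- length(sequence)
  if (n == 0) stop("empty sequence", call. = FALSE)
  backbone <- vector("list", n)
  # first residue: N at origin, CA on +x, C in the xy-plane
  N <- c(0, 0, 0)
  CA <- c(.BB$b_n_ca, 0, 0)
  th <- .BB$a_n_ca_c * pi / 180
  C <- CA + .BB$b_ca_c * c(-cos(th), sin(th), 0)
  for (i in seq_len(n)) {
    O <- place_atom(N, CA, C, .BB$b_c_o, .BB$a_ca_c_o, .BB$psi + 180)
    backbone[[i]] <- list(N = N, CA = CA, C = C, O = O)
    if (i < n) {
      N2 <- place_atom(N, CA, C, .BB$b_c_n, .BB$a_ca_c_n, .BB$psi)
      CA2 <- place_atom(CA, C, N2, .BB$b_n_ca, .BB$a_c_n_ca, .BB$omega)
      C2 <- place_atom(C, N2, CA2, .BB$b_ca_c, .BB$a_n_ca_c, .BB$phi)
      N <- N2; CA <- CA2; C <- C2
    }
  }
  .assemble_peptide(sequence, backbone)
}

#' The native huntingtin N-terminal 17-mer sequence
#'
#' @return `"MATLEKLMKAFESLKSF"`, the 17-residue N-terminal segment of
#'   huntingtin exon 1 preceding the polyglutamine tract.
#' @export
htt_nterm_sequence <- function() "MATLEKLMKAFESLKSF"

#' Parse mutation notation
#'
#' Parses whitespace-separated, case-insensitive mutation strings such as
#' `"L4K E12K K15E"` into a data.frame of mutation specifications.
#'
#' @param text Character string (or vector of single-mutation strings).
#' @return data.frame with columns `position`, `wild_type`, `mutant`.
#' @export
parse_mutations <- function(text) {
  toks <- unlist(strsplit(toupper(trimws(text)), "\\s+"))
  toks <- toks[nzchar(toks)]
  if (length(toks) == 0) {
    return(data.frame(position = integer(), wild_type = character(),
                      mutant = character(), stringsAsFactors = FALSE))
  }
  ok <- grepl("^[A-Z][0-9]+[A-Z]$", toks)
  if (any(!ok)) {
    stop("unparseable mutation token(s): ", paste(toks[!ok], collapse = ", "),
         call. = FALSE)
  }
  wt <- as_residue_vector(substr(toks, 1, 1))
  mut <- as_residue_vector(substring(toks, nchar(toks)))
  pos <- as.integer(gsub("^[A-Z]|[A-Z]$", "", toks))
  data.frame(position = pos, wild_type = wt, mutant = mut,
             stringsAsFactors = FALSE)
}

#' @rdname parse_mutations
#' @param muts Parsed mutation data.frame.
#' @return `format_mutations` returns the string notation.
#' @export
format_mutations <- function(muts) {
  paste0(muts$wild_type, muts$position, muts$mutant, collapse = " ")
}

# Normalize a mutation argument (string or data.frame) to the parsed form.
as_mutation_frame <- function(mutation) {
  if (is.character(mutation)) mutation <- parse_mutations(mutation)
  stopifnot(all(c("position", "wild_type", "mutant") %in% names(mutation)))
  mutation
}

#' Apply a point mutation on a fixed backbone
#'
#' Replaces the side chain at the mutated position with the mutant
#' residue's template rotamer while leaving every backbone atom
#' coordinate bit-identical and every other residue untouched. The
#' wild-type letter must match the peptide's sequence at the position.
#' An identity "mutation" (wild type equals mutant) returns the peptide
#' unchanged.
#'
#' @param pep A [peptide()].
#' @param mutation A single mutation, either a string like `"L4K"` or a
#'   one-row data.frame from [parse_mutations()]. A multi-mutation string
#'   is applied left to right.
#' @return The mutated [peptide()].
#' @export
apply_mutation <- function(pep, mutation) {
  muts <- as_mutation_frame(mutation)
  for (k in seq_len(nrow(muts))) {
    pep <- .apply_one_mutation(pep, muts$position[k], muts$wild_type[k],
                               muts$mutant[k])
  }
  pep
}

.apply_one_mutation <- function(pep, position, wild_type, mutant) {
  n <- length(pep$sequence)
  if (position < 1 || position > n) {
    stop("mutation position ", position, " outside sequence of length ", n,
         call. = FALSE)
  }
  found <- pep$sequence[position]
  if (found != wild_type) {
    stop("wild-type mismatch at position ", position, ": expected ",
         wild_type, ", found ", found, call. = FALSE)
  }
  if (wild_type == mutant) return(pep)
  sequence <- pep$sequence
  sequence[position] <- mutant
  # rebuild from existing backbone coordinates; only the mutated residue's
  # side chain changes, and all backbone atoms are reused verbatim
  backbone <- lapply(seq_len(n), function(i) {
    sel <- pep$atoms$residue_index == i
    a <- pep$atoms[sel, ]
    lapply(structure(c("N", "CA", "C", "O"), names = c("N", "CA", "C", "O")),
           function(nm) unlist(a[a$name == nm, c("x", "y", "z")], use.names = FALSE))
  })
  out <- .assemble_peptide(sequence, backbone)
  # keep non-mutated side-chain coordinates exactly as they were
  for (i in setdiff(seq_len(n), position)) {
    old <- pep$atoms[pep$atoms$residue_index == i, ]
    sel <- out$atoms$residue_index == i
    stopifnot(identical(out$atoms$name[sel], old$name))
    out$atoms[sel, c("x", "y", "z")] <- old[, c("x", "y", "z")]
  }
  out
}
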