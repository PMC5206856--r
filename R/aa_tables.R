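# Canonical amino-acid bookkeeping and embedded per-residue scales.

#' The 20 canonical amino acids (one-letter codes)
#'
#' @return Character vector of the 20 canonical one-letter residue codes,
#'   alphabetical.
#' @export
canonical_residues <- function() {
  c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
    "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
}

.AA3 <- c(A = "ALA", C = "CYS", D = "ASP", E = "GLU", F = "PHE", G = "GLY",
          H = "HIS", I = "ILE", K = "LYS", L = "LEU", M = "MET", N = "ASN",
          P = "PRO", Q = "GLN", R = "ARG", S = "SER", T = "THR", V = "VAL",
          W = "TRP", Y = "TYR")
.AA1 <- structure(names(.AA3), names = .AA3)

# Formal side-chain charges at neutral pH: D/E deprotonated, K/R protonated,
# H neutral. Termini are modelled uncharged.
.FORMAL_CHARGE <- c(A = 0, C = 0, D = -1, E = -1, F = 0, G = 0, H = 0, I = 0,
                    K = 1, L = 0, M = 0, N = 0, P = 0, Q = 0, R = 1, S = 0,
                    T = 0, V = 0, W = 0, Y = 0)

# Kyte-Doolittle hydropathy (J Mol Biol 1982, 157:105-132).
.KD_HYDROPATHY <- c(A = 1.8, C = 2.5, D = -3.5, E = -3.5, F = 2.8, G = -0.4,
                    H = -3.2, I = 4.5, K = -3.9, L = 3.8, M = 1.9, N = -3.5,
                    P = -1.6, Q = -3.5, R = -4.5, S = -0.8, T = -0.7,
                    V = 4.2, W = -0.9, Y = -1.3)

# Chou-Fasman secondary-structure propensities (Biochemistry 1974, 13:222).
.CF_HELIX <- c(A = 1.42, C = 0.70, D = 1.01, E = 1.51, F = 1.13, G = 0.57,
               H = 1.00, I = 1.08, K = 1.16, L = 1.21, M = 1.45, N = 0.67,
               P = 0.57, Q = 1.11, R = 0.98, S = 0.77, T = 0.83, V = 1.06,
               W = 1.08, Y = 0.69)
.CF_BETA <- c(A = 0.83, C = 1.19, D = 0.54, E = 0.37, F = 1.38, G = 0.75,
              H = 0.87, I = 1.60, K = 0.74, L = 1.30, M = 1.05, N = 0.89,
              P = 0.55, Q = 1.10, R = 0.93, S = 0.75, T = 1.19, V = 1.70,
              W = 1.37, Y = 1.47)

#' Formal side-chain charge of each canonical residue
#'
#' K and R carry +1, D and E carry -1, all other residues (including
#' histidine, taken neutral at pH 7) carry 0. Termini are ignored.
#'
#' @param residues Character vector of one-letter codes.
#' @return Integer vector of formal charges.
#' @export
residue_formal_charge <- function(residues) {
  residues <- as_residue_vector(residues)
  as.integer(.FORMAL_CHARGE[residues])
}

# Normalize a sequence given as a single string or a character vector of
# one-letter codes; validates against the canonical 20.
as_residue_vector <- function(sequence) {
  if (length(sequence) == 1L && nchar(sequence[1]) != 1L) {
    sequence <- strsplit(sequence, "")[[1]]
  }
  sequence <- toupper(sequence)
  bad <- setdiff(unique(sequence), canonical_residues())
  if (length(bad) > 0) {
    stop("non-canonical residue code(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  sequence
}

aa_three_letter <- function(one) unname(.AA3[one])
aa_one_letter <- function(three) {
  out <- unname(.AA1[toupper(three)])
  if (anyNA(out)) {
    stop("unknown residue name(s): ",
         paste(unique(three[is.na(out)]), collapse = ", "), call. = FALSE)
  }
  out
}
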