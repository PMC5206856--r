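# Embedded heavy-atom (united-atom) parameter set, version 1.
#
# The set is self-contained and versioned so that every energy in the
# package is reproducible from the source tree alone. Aliphatic and
# aromatic hydrogens are folded into their parent carbons (united-atom
# convention); polar hydrogens are folded into N/O classes. LJ parameters
# use Lorentz-Berthelot combining downstream (arithmetic sigma, geometric
# epsilon). Atomic solvation parameters follow the sign convention of
# Eisenberg-McLachlan-type models: positive for apolar atoms (exposure
# penalized), negative for polar/charged atoms (exposure favored),
# in kcal/(mol A^2).

PARAMETER_SET_VERSION <- "httscan-ua-1"

# class, sigma (A), epsilon (kcal/mol), vdw radius for SASA (A),
# solvation parameter (kcal/(mol A^2)), element
.ATOM_CLASSES <- data.frame(
  class   = c("C",   "CH1", "CH2", "CH3", "CAro", "N",    "NL",   "O",
              "OM",  "OA",  "S"),
  sigma   = c(3.75,  3.80,  3.90,  3.75,  3.70,   3.25,   3.25,   2.96,
              2.96,  3.00,  3.55),
  epsilon = c(0.105, 0.090, 0.118, 0.175, 0.110,  0.170,  0.170,  0.210,
              0.250, 0.200, 0.250),
  vdw     = c(1.70,  1.90,  1.90,  1.95,  1.85,   1.65,   1.65,   1.50,
              1.50,  1.55,  1.80),
  solv    = c(0.016, 0.016, 0.016, 0.016, 0.016, -0.006, -0.050, -0.006,
             -0.024, -0.006, 0.021),
  element = c("C", "C", "C", "C", "C", "N", "N", "O", "O", "O", "S"),
  stringsAsFactors = FALSE
)
rownames(.ATOM_CLASSES) <- .ATOM_CLASSES$class

# Backbone partial charges (sum to 0 per residue); side-chain charges are
# defined per residue below and sum to the residue's formal charge.
.BACKBONE_CHARGE <- c(N = -0.28, CA = 0.28, C = 0.38, O = -0.38)

.SIDECHAIN_CHARGE <- list(
  C = c(CB = 0.20, SG = -0.20),
  D = c(CG = 0.40, OD1 = -0.70, OD2 = -0.70),
  E = c(CD = 0.40, OE1 = -0.70, OE2 = -0.70),
  H = c(ND1 = -0.30, CE1 = 0.30),
  K = c(CE = 0.30, NZ = 0.70),
  M = c(CG = 0.10, SD = -0.20, CE = 0.10),
  N = c(CG = 0.38, OD1 = -0.38),
  Q = c(CD = 0.38, OE1 = -0.38),
  R = c(CZ = 0.40, NH1 = 0.30, NH2 = 0.30),
  S = c(CB = 0.30, OG = -0.30),
  T = c(CB = 0.30, OG1 = -0.30),
  W = c(CD1 = 0.15, NE1 = -0.30, CE2 = 0.15),
  Y = c(CZ = 0.30, OH = -0.30)
)

# Side-chain internal-coordinate templates: one most-common rotamer per
# residue type. Each atom is placed by natural-extension (NeRF) from three
# previously placed reference atoms a-b-c of the same residue, with c the
# bonded parent: bond = c-atom distance (A), angle = b-c-atom (deg),
# dihedral = a-b-c-atom (deg). CB uses the backbone frame (C, N, CA) with
# the L-chirality constant -120 deg. chi1 defaults to the gauche- slot
# (-60 deg) except where the trans rotamer is the common one (V).
.tpl <- function(name, class, a, b, c, bond, angle, dihedral) {
  data.frame(name = name, class = class, a = a, b = b, c = c,
             bond = bond, angle = angle, dihedral = dihedral,
             stringsAsFactors = FALSE)
}
.cb <- function(class = "CH2", angle = 110.5, bond = 1.530, dihedral = -120) {
  .tpl("CB", class, "C", "N", "CA", bond, angle, dihedral)
}

.SIDECHAIN_TEMPLATES <- list(
  A = .cb("CH3"),
  C = rbind(.cb(),
            .tpl("SG", "S", "N", "CA", "CB", 1.808, 114.0, -60)),
  D = rbind(.cb(),
            .tpl("CG",  "C",  "N",  "CA", "CB", 1.516, 112.6, -60),
            .tpl("OD1", "OM", "CA", "CB", "CG", 1.249, 118.4, -20),
            .tpl("OD2", "OM", "CA", "CB", "CG", 1.249, 118.4, 160)),
  E = rbind(.cb(),
            .tpl("CG",  "CH2", "N",  "CA", "CB", 1.520, 114.1, -60),
            .tpl("CD",  "C",   "CA", "CB", "CG", 1.516, 112.6, 180),
            .tpl("OE1", "OM",  "CB", "CG", "CD", 1.249, 118.4, -20),
            .tpl("OE2", "OM",  "CB", "CG", "CD", 1.249, 118.4, 160)),
  F = rbind(.cb(),
            .tpl("CG",  "C",    "N",  "CA",  "CB",  1.502, 113.8, -60),
            .tpl("CD1", "CAro", "CA", "CB",  "CG",  1.391, 120.7, 90),
            .tpl("CD2", "CAro", "CA", "CB",  "CG",  1.391, 120.7, -90),
            .tpl("CE1", "CAro", "CB", "CG",  "CD1", 1.393, 120.7, 180),
            .tpl("CE2", "CAro", "CB", "CG",  "CD2", 1.393, 120.7, 180),
            .tpl("CZ",  "CAro", "CG", "CD1", "CE1", 1.390, 120.0, 0)),
  G = NULL,
  H = rbind(.cb(),
            .tpl("CG",  "C",    "N",  "CA", "CB",  1.497, 113.8, -60),
            .tpl("ND1", "N",    "CA", "CB", "CG",  1.380, 122.7, -75),
            .tpl("CD2", "CAro", "CA", "CB", "CG",  1.356, 131.0, 105),
            .tpl("CE1", "CAro", "CB", "CG", "ND1", 1.324, 109.3, 180),
            .tpl("NE2", "N",    "CB", "CG", "CD2", 1.374, 107.2, 180)),
  I = rbind(.cb("CH1"),
            .tpl("CG1", "CH2", "N",  "CA", "CB",  1.530, 110.4, -60),
            .tpl("CG2", "CH3", "N",  "CA", "CB",  1.521, 110.5, 60),
            .tpl("CD1", "CH3", "CA", "CB", "CG1", 1.513, 113.8, 180)),
  K = rbind(.cb(),
            .tpl("CG", "CH2", "N",  "CA", "CB", 1.520, 114.1, -60),
            .tpl("CD", "CH2", "CA", "CB", "CG", 1.520, 111.3, 180),
            .tpl("CE", "CH2", "CB", "CG", "CD", 1.520, 111.3, 180),
            .tpl("NZ", "NL",  "CG", "CD", "CE", 1.489, 111.9, 180)),
  L = rbind(.cb(),
            .tpl("CG",  "CH1", "N",  "CA", "CB", 1.530, 116.3, -60),
            .tpl("CD1", "CH3", "CA", "CB", "CG", 1.521, 110.7, 180),
            .tpl("CD2", "CH3", "CA", "CB", "CG", 1.521, 110.7, 60)),
  M = rbind(.cb(),
            .tpl("CG", "CH2", "N",  "CA", "CB", 1.520, 114.1, -60),
            .tpl("SD", "S",   "CA", "CB", "CG", 1.803, 112.7, 180),
            .tpl("CE", "CH3", "CB", "CG", "SD", 1.791, 100.9, 180)),
  N = rbind(.cb(),
            .tpl("CG",  "C", "N",  "CA", "CB", 1.516, 112.6, -60),
            .tpl("OD1", "O", "CA", "CB", "CG", 1.231, 120.8, -20),
            .tpl("ND2", "N", "CA", "CB", "CG", 1.328, 116.4, 160)),
  P = rbind(.cb("CH2", angle = 103.0),
            .tpl("CG", "CH2", "N",  "CA", "CB", 1.492, 104.5, -25),
            .tpl("CD", "CH2", "CA", "CB", "CG", 1.503, 106.1, 38)),
  Q = rbind(.cb(),
            .tpl("CG",  "CH2", "N",  "CA", "CB", 1.520, 114.1, -60),
            .tpl("CD",  "C",   "CA", "CB", "CG", 1.516, 112.6, 180),
            .tpl("OE1", "O",   "CB", "CG", "CD", 1.231, 120.8, -20),
            .tpl("NE2", "N",   "CB", "CG", "CD", 1.328, 116.4, 160)),
  R = rbind(.cb(),
            .tpl("CG",  "CH2", "N",  "CA", "CB", 1.520, 114.1, -60),
            .tpl("CD",  "CH2", "CA", "CB", "CG", 1.520, 111.3, 180),
            .tpl("NE",  "N",   "CB", "CG", "CD", 1.460, 111.8, 180),
            .tpl("CZ",  "C",   "CG", "CD", "NE", 1.330, 124.2, 180),
            .tpl("NH1", "NL",  "CD", "NE", "CZ", 1.326, 120.0, 0),
            .tpl("NH2", "NL",  "CD", "NE", "CZ", 1.326, 120.0, 180)),
  S = rbind(.cb(),
            .tpl("OG", "OA", "N", "CA", "CB", 1.417, 110.8, -60)),
  T = rbind(.cb("CH1"),
            .tpl("OG1", "OA",  "N", "CA", "CB", 1.433, 109.6, -60),
            .tpl("CG2", "CH3", "N", "CA", "CB", 1.521, 110.5, 60)),
  V = rbind(.cb("CH1"),
            .tpl("CG1", "CH3", "N", "CA", "CB", 1.521, 110.5, 180),
            .tpl("CG2", "CH3", "N", "CA", "CB", 1.521, 110.5, -60)),
  W = rbind(.cb(),
            .tpl("CG",  "C",    "N",   "CA",  "CB",  1.498, 113.6, -60),
            .tpl("CD1", "CAro", "CA",  "CB",  "CG",  1.365, 126.9, 90),
            .tpl("CD2", "C",    "CA",  "CB",  "CG",  1.433, 126.6, -90),
            .tpl("NE1", "N",    "CB",  "CG",  "CD1", 1.374, 110.2, 180),
            .tpl("CE2", "C",    "CB",  "CG",  "CD2", 1.409, 107.2, 180),
            .tpl("CE3", "CAro", "CB",  "CG",  "CD2", 1.398, 133.9, 0),
            .tpl("CZ2", "CAro", "CG",  "CD2", "CE2", 1.394, 122.4, 180),
            .tpl("CZ3", "CAro", "CG",  "CD2", "CE3", 1.391, 118.6, 180),
            .tpl("CH2", "CAro", "CD2", "CE2", "CZ2", 1.368, 117.5, 0)),
  Y = rbind(.cb(),
            .tpl("CG",  "C",    "N",   "CA",  "CB",  1.502, 113.8, -60),
            .tpl("CD1", "CAro", "CA",  "CB",  "CG",  1.391, 120.7, 90),
            .tpl("CD2", "CAro", "CA",  "CB",  "CG",  1.391, 120.7, -90),
            .tpl("CE1", "CAro", "CB",  "CG",  "CD1", 1.393, 120.7, 180),
            .tpl("CE2", "CAro", "CB",  "CG",  "CD2", 1.393, 120.7, 180),
            .tpl("CZ",  "CAro", "CG",  "CD1", "CE1", 1.390, 120.0, 0),
            .tpl("OH",  "OA",   "CD1", "CE1", "CZ",  1.376, 119.9, 180))
)

# Intra-residue bonds not implied by the template parent chain
# (ring closures); proline's CD-N closes onto the backbone nitrogen.
.RING_BONDS <- list(
  F = matrix(c("CE2", "CZ"), ncol = 2, byrow = TRUE),
  Y = matrix(c("CE2", "CZ"), ncol = 2, byrow = TRUE),
  W = matrix(c("NE1", "CE2", "CZ3", "CH2"), ncol = 2, byrow = TRUE),
  H = matrix(c("CE1", "NE2"), ncol = 2, byrow = TRUE),
  P = matrix(c("CD", "N"), ncol = 2, byrow = TRUE)
)

# Heavy-atom names of a residue: backbone + template side chain.
residue_atom_names <- function(res) {
  c("N", "CA", "C", "O", .SIDECHAIN_TEMPLATES[[res]]$name)
}

# Partial charge of every atom of a residue, named by atom name.
residue_charges <- function(res) {
  ch <- .BACKBONE_CHARGE
  sc <- .SIDECHAIN_TEMPLATES[[res]]
  if (!is.null(sc)) {
    sccharge <- structure(numeric(nrow(sc)), names = sc$name)
    override <- .SIDECHAIN_CHARGE[[res]]
    if (!is.null(override)) sccharge[names(override)] <- override
    ch <- c(ch, sccharge)
  }
  ch
}

# Atom class of every atom of a residue (backbone CA is CH1, CH2 for Gly).
residue_atom_classes <- function(res) {
  cls <- c(N = "N", CA = if (res == "G") "CH2" else "CH1", C = "C", O = "O")
  sc <- .SIDECHAIN_TEMPLATES[[res]]
  if (!is.null(sc)) cls <- c(cls, structure(sc$class, names = sc$name))
  cls
}

#' The embedded atom-class parameter table
#'
#' Returns the versioned united-atom parameter table used throughout the
#' package: per-class Lennard-Jones sigma/epsilon, van der Waals radius
#' (for solvent-accessible surface area), atomic solvation parameter and
#' element.
#'
#' @return A data.frame with one row per atom class.
#' @export
atom_parameter_table <- function() {
  out <- .ATOM_CLASSES
  attr(out, "version") <- PARAMETER_SET_VERSION
  out
}
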