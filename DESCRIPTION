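Package: httscan
Title: Mutational Stability Landscapes and Mutant Design for the
    Huntingtin N-Terminal Helix
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Desk-scale mutational scanning of the 17-residue huntingtin
    N-terminal helix (MATLEKLMKAFESLKSF). Builds idealized alpha-helical
    peptide models, evaluates a decomposed stability energy
    (Lennard-Jones + Coulomb + SASA-weighted implicit solvation),
    produces the exhaustive single-point mutation energy landscape,
    estimates multi-point mutant stability additively, scores sequences
    with compositional physicochemical features, and applies a
    three-criteria candidate filter (stability rank, hydrophobic-to-
    charged replacement, oligomer-contact breaking at positions 6/15).
    Also provides RMSD/RMSF trajectory statistics with optimal rigid
    superposition and a seeded synthetic-trajectory generator.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    bio3d,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
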