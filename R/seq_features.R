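# Compositional sequence features: net charge, hydrophobicity,
# secondary-structure propensities and a composite aggregation score.
# All features are permutation-invariant (they depend on composition
# only), a documented limitation relative to window-based aggregation
# predictors.

.HYDRO_SCALES <- list(kd = .KD_HYDROPATHY)

#' Available hydrophobicity scales
#' @return Character vector of scale names.
#' @export
hydrophobicity_scales <- function() names(.HYDRO_SCALES)

#' Net formal charge of a sequence
#'
#' `(#K + #R) - (#D + #E)`; histidine counts 0 and termini are ignored.
#'
#' @param sequence Character string or vector of one-letter codes.
#' @return Integer net charge in elementary charge units.
#' @examples
#' net_charge("MATLEKLMKAFESLKSF")  # +1
#' @export
net_charge <- function(sequence) {
  sum(residue_formal_charge(as_residue_vector(sequence)))
}

#' Mean hydrophobicity
#'
#' Arithmetic mean of per-residue hydrophobicity values under a named
#' scale (default `"kd"`, Kyte-Doolittle hydropathy).
#'
#' @param sequence Character string or vector of one-letter codes.
#' @param scale Scale name (see [hydrophobicity_scales()]) or a named
#'   numeric vector covering all 20 residues.
#' @return Mean hydrophobicity (scale units).
#' @export
mean_hydrophobicity <- function(sequence, scale = "kd") {
  sequence <- as_residue_vector(sequence)
  if (is.character(scale)) {
    if (!scale %in% names(.HYDRO_SCALES)) {
      stop("unknown hydrophobicity scale '", scale, "'; available: ",
           paste(hydrophobicity_scales(), collapse = ", "), call. = FALSE)
    }
    scale <- .HYDRO_SCALES[[scale]]
  }
  if (!all(canonical_residues() %in% names(scale))) {
    stop("hydrophobicity scale must cover all 20 residues", call. = FALSE)
  }
  mean(scale[sequence])
}

#' Helix and sheet propensities
#'
#' Arithmetic means of the embedded Chou-Fasman per-residue
#' alpha-helix and beta-sheet propensity tables.
#'
#' @param sequence Character string or vector of one-letter codes.
#' @return Named numeric vector `c(helix_propensity, beta_propensity)`.
#' @export
secondary_propensity <- function(sequence) {
  sequence <- as_residue_vector(sequence)
  c(helix_propensity = mean(.CF_HELIX[sequence]),
    beta_propensity = mean(.CF_BETA[sequence]))
}

#' Composite aggregation-propensity score
#'
#' A configurable stand-in for external aggregation predictors: a linear
#' combination of z-scored compositional features,
#' `w_h z(hydrophobicity) + w_q z(-|mean charge|) + w_b z(beta) - w_a z(helix)`,
#' where each feature is z-scored against the mean and standard deviation
#' of its per-residue table over the 20 canonical residues. Higher values
#' indicate higher aggregation propensity; the score is monotone
#' increasing in hydrophobicity for positive `hydrophobicity` weight.
#' This score does not reproduce the numbers of any external predictor.
#'
#' @param sequence Character string or vector of one-letter codes.
#' @param weights Named coefficients; must contain `hydrophobicity`,
#'   `charge`, `beta` and `helix` (defaults all 1).
#' @param scale Hydrophobicity scale name (default `"kd"`).
#' @return Dimensionless score.
#' @export
aggregation_score <- function(sequence,
                              weights = c(hydrophobicity = 1, charge = 1,
                                          beta = 1, helix = 1),
                              scale = "kd") {
  need <- c("hydrophobicity", "charge", "beta", "helix")
  missing_w <- setdiff(need, names(weights))
  if (length(missing_w) > 0) {
    stop("missing aggregation weight(s): ", paste(missing_w, collapse = ", "),
         call. = FALSE)
  }
  sequence <- as_residue_vector(sequence)
  hs <- .HYDRO_SCALES[[scale]]
  z <- function(x, tab) (x - mean(tab)) / sd(tab)
  n <- length(sequence)
  score_h <- z(mean_hydrophobicity(sequence, scale), hs)
  score_q <- z(-abs(net_charge(sequence)) / n, .FORMAL_CHARGE)
  sp <- secondary_propensity(sequence)
  score_b <- z(sp[["beta_propensity"]], .CF_BETA)
  score_a <- z(sp[["helix_propensity"]], .CF_HELIX)
  unname(weights["hydrophobicity"] * score_h + weights["charge"] * score_q +
           weights["beta"] * score_b - weights["helix"] * score_a)
}

#' Full feature row for a sequence
#'
#' @param sequence Character string or vector of one-letter codes.
#' @param id Row identifier.
#' @inheritParams aggregation_score
#' @return One-row data.frame with columns id, sequence,
#'   mean_hydrophobicity, net_charge, beta_propensity, helix_propensity,
#'   aggregation_score (mirroring the order of external predictor
#'   reports).
#' @export
sequence_features <- function(sequence, id = "seq",
                              weights = c(hydrophobicity = 1, charge = 1,
                                          beta = 1, helix = 1),
                              scale = "kd") {
  sequence <- as_residue_vector(sequence)
  sp <- secondary_propensity(sequence)
  data.frame(id = id, sequence = paste(sequence, collapse = ""),
             mean_hydrophobicity = mean_hydrophobicity(sequence, scale),
             net_charge = net_charge(sequence),
             beta_propensity = sp[["beta_propensity"]],
             helix_propensity = sp[["helix_propensity"]],
             aggregation_score = aggregation_score(sequence, weights, scale),
             stringsAsFactors = FALSE)
}

#' Write a feature table as TSV
#'
#' @param features data.frame of [sequence_features()] rows.
#' @param path Output file.
#' @export
write_features <- function(features, path) {
  write.table(features, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
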