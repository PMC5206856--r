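#' @useDynLib httscan, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats coef lm.fit rnorm sd setNames
#' @importFrom utils combn read.table write.table
NULL

.onLoad <- function(libname, pkgname) {
  register_solvation_model("sasa", .sasa_solvation)
}
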