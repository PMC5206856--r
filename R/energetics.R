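# Decomposed stability energy: E = solvation + Lennard-Jones + Coulomb,
# plus steepest-descent relaxation.

#' Solvation model configuration
#'
#' Parameters of the implicit-solvation term. The default backend
#' (`model = "sasa"`) is a SASA-weighted atomic solvation model: the
#' energy is the sum over atoms of the atomic solvation parameter times
#' the atom's solvent-accessible surface area, computed with the stated
#' probe radius. The dipolar-solvent fields (`dipole_moment_p0`,
#' `dipole_concentration_Cdip`, `grid_spacing_a`) are documentation-only
#' descriptors of the solvent model the configuration stands for; the
#' default backend does not consume them, but alternative backends
#' registered via [register_solvation_model()] may.
#'
#' @param probe_radius Solvent probe radius in Angstrom (default 1.4).
#' @param temperature Temperature in Kelvin (default 300).
#' @param dipole_moment_p0 Solvent dipole moment, Debye (default 3.00).
#' @param dipole_concentration_Cdip Solvent dipole concentration, mol/L
#'   (default 55).
#' @param grid_spacing_a Solvent lattice spacing, Angstrom (default 2.8).
#' @param model Identifier of the solvation backend (default `"sasa"`).
#' @param n_sphere_points Sphere points per atom for the SASA estimate
#'   (default 960; deterministic golden-section spiral).
#' @return A `solvation_config` object.
#' @export
solvation_config <- function(probe_radius = 1.4, temperature = 300,
                             dipole_moment_p0 = 3.00,
                             dipole_concentration_Cdip = 55,
                             grid_spacing_a = 2.8, model = "sasa",
                             n_sphere_points = 960) {
  stopifnot(probe_radius > 0, temperature > 0)
  structure(list(probe_radius = probe_radius, temperature = temperature,
                 dipole_moment_p0 = dipole_moment_p0,
                 dipole_concentration_Cdip = dipole_concentration_Cdip,
                 grid_spacing_a = grid_spacing_a, model = model,
                 n_sphere_points = n_sphere_points),
            class = "solvation_config")
}

#' Energy model configuration
#'
#' @param cutoff Distance cutoff in Angstrom for LJ and Coulomb pair
#'   interactions (default 10). `Inf` or values <= 0 are rejected.
#' @param relative_permittivity Dimensionless relative permittivity for
#'   the Coulomb term (default 1).
#' @param coulomb_constant Coulomb prefactor in kcal A / (mol e^2)
#'   (default 332.0636).
#' @param solvation A [solvation_config()].
#' @return An `energy_config` object.
#' @export
energy_config <- function(cutoff = 10, relative_permittivity = 1,
                          coulomb_constant = 332.0636,
                          solvation = solvation_config()) {
  stopifnot(is.finite(cutoff), cutoff > 0, relative_permittivity >= 1)
  structure(list(cutoff = cutoff,
                 relative_permittivity = relative_permittivity,
                 coulomb_constant = coulomb_constant,
                 solvation = solvation),
            class = "energy_config")
}

# Canonical provenance string of a configuration (recorded on landscape
# tables so estimates cannot mix incompatible energy models).
config_provenance <- function(config) {
  s <- config$solvation
  paste0("params=", PARAMETER_SET_VERSION,
         ";cutoff=", format(config$cutoff),
         ";eps_r=", format(config$relative_permittivity),
         ";k=", format(config$coulomb_constant),
         ";probe=", format(s$probe_radius), ";T=", format(s$temperature),
         ";model=", s$model, ";npts=", format(s$n_sphere_points))
}

# Non-bonded pair list with 1-2/1-3 and same-residue exclusions; 1-4 and
# beyond interact fully. Cached on the peptide (coordinates do not affect
# the pair list).
nb_pairs <- function(pep, config) {
  ckey <- paste(config$coulomb_constant, config$relative_permittivity)
  cache <- attr(pep, "nb_cache")
  if (!is.null(cache) && identical(cache$ckey, ckey)) return(cache)
  n <- nrow(pep$atoms)
  adj <- vector("list", n)
  for (k in seq_len(nrow(pep$bonds))) {
    a <- pep$bonds[k, 1]; b <- pep$bonds[k, 2]
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  excl <- matrix(FALSE, n, n)
  # same residue
  for (i in seq_along(pep$sequence)) {
    idx <- which(pep$atoms$residue_index == i)
    excl[idx, idx] <- TRUE
  }
  # bond distance 1 and 2
  for (a in seq_len(n)) {
    nb <- adj[[a]]
    excl[a, nb] <- TRUE
    excl[nb, a] <- TRUE
    if (length(nb) > 1) {
      excl[nb, nb] <- TRUE
    } else if (length(nb) == 1) {
      excl[nb, nb] <- TRUE
    }
  }
  ut <- upper.tri(excl)
  keep <- which(ut & !excl, arr.ind = TRUE)
  i <- keep[, 1]; j <- keep[, 2]
  at <- pep$atoms
  pairs <- list(
    i = i, j = j,
    sigma = (at$lj_sigma[i] + at$lj_sigma[j]) / 2,
    epsilon = sqrt(at$lj_epsilon[i] * at$lj_epsilon[j]),
    qq = config$coulomb_constant * at$charge[i] * at$charge[j] /
      config$relative_permittivity,
    ckey = ckey
  )
  pairs
}

# Attach the pair cache so repeated energy calls skip the O(n^2) setup.
with_nb_cache <- function(pep, config) {
  attr(pep, "nb_cache") <- nb_pairs(pep, config)
  pep
}

#' Lennard-Jones energy
#'
#' Sum over non-excluded atom pairs within the cutoff of
#' `4 eps_ij ((sig_ij/r)^12 - (sig_ij/r)^6)` with Lorentz-Berthelot
#' combining (arithmetic sigma, geometric epsilon). Pairs within the same
#' residue or separated by fewer than 3 bonds are excluded.
#'
#' @param pep A [peptide()].
#' @param config An [energy_config()].
#' @return Energy in kcal/mol.
#' @export
lj_energy <- function(pep, config = energy_config()) {
  p <- nb_pairs(pep, config)
  .nb_energy_cpp(peptide_coords(pep), p$i, p$j, p$sigma, p$epsilon, p$qq,
                 config$cutoff)$lj
}

#' Coulomb energy
#'
#' Sum over non-excluded atom pairs within the cutoff of
#' `k q_i q_j / (eps_r r)` with `k` the Coulomb constant of the
#' configuration. Exclusions are as in [lj_energy()].
#'
#' @inheritParams lj_energy
#' @return Energy in kcal/mol.
#' @export
coulomb_energy <- function(pep, config = energy_config()) {
  p <- nb_pairs(pep, config)
  .nb_energy_cpp(peptide_coords(pep), p$i, p$j, p$sigma, p$epsilon, p$qq,
                 config$cutoff)$coulomb
}

#' Toy atom cloud
#'
#' Builds a minimal peptide-like object from bare atoms (each atom its
#' own pseudo-residue, no bonds, no exclusions), so the energy kernels
#' can be exercised and verified on hand-constructed configurations.
#'
#' @param coords `n x 3` coordinate matrix, Angstrom.
#' @param lj_sigma,lj_epsilon LJ parameters, recycled over atoms.
#' @param charge Partial charges, recycled.
#' @param solvation_param Atomic solvation parameters, recycled.
#' @param vdw_radius van der Waals radii, recycled.
#' @return An object usable wherever a [peptide()] is expected by the
#'   energy functions.
#' @export
atom_cloud <- function(coords, lj_sigma = 3.5, lj_epsilon = 0.2,
                       charge = 0, solvation_param = 0, vdw_radius = 1.7) {
  coords <- as.matrix(coords)
  n <- nrow(coords)
  atoms <- data.frame(
    name = paste0("X", seq_len(n)), class = "X", element = "C",
    residue_index = seq_len(n),
    x = coords[, 1], y = coords[, 2], z = coords[, 3],
    charge = rep_len(charge, n),
    lj_sigma = rep_len(lj_sigma, n),
    lj_epsilon = rep_len(lj_epsilon, n),
    solvation_param = rep_len(solvation_param, n),
    vdw_radius = rep_len(vdw_radius, n),
    stringsAsFactors = FALSE
  )
  structure(list(sequence = rep("G", n), atoms = atoms,
                 bonds = matrix(integer(), ncol = 2)),
            class = "peptide")
}

# Rotate centered coordinates into a deterministic principal-axes frame
# so that the sphere-point SASA estimate is exactly invariant under
# proper rigid motions of the input (frame ambiguities only arise for
# degenerate, symmetric clouds).
.canonical_frame <- function(coords) {
  coords <- sweep(coords, 2, colMeans(coords))
  if (nrow(coords) >= 3) {
    ev <- eigen(crossprod(coords), symmetric = TRUE)$vectors
    # fix each axis sign from the point distribution itself (projection
    # skewness, falling back to the largest projection), so the frame is
    # identical for any proper rigid motion of the same cloud
    for (k in 1:3) {
      p <- coords %*% ev[, k]
      s <- sum(p^3)
      if (abs(s) < 1e-9) s <- p[which.max(abs(p))]
      if (s < 0) ev[, k] <- -ev[, k]
    }
    if (det(ev) < 0) ev[, 3] <- -ev[, 3]
    coords <- coords %*% ev
  }
  coords
}

#' Solvent-accessible surface area (Shrake-Rupley)
#'
#' Per-atom solvent-accessible surface area from a deterministic
#' golden-section spiral point set rolled over the atoms' van der Waals
#' spheres inflated by the probe radius.
#'
#' @param pep A [peptide()].
#' @param probe_radius Probe radius in Angstrom (default 1.4).
#' @param n_sphere_points Points per atom (default 960; must be >= 100).
#' @return Numeric vector of per-atom areas in A^2 (attribute `total`
#'   carries the sum).
#' @export
sasa <- function(pep, probe_radius = 1.4, n_sphere_points = 960) {
  stopifnot(n_sphere_points >= 100)
  radii <- pep$atoms$vdw_radius + probe_radius
  a <- .sasa_cpp(.canonical_frame(peptide_coords(pep)), radii,
                 as.integer(n_sphere_points))
  attr(a, "total") <- sum(a)
  a
}

# Registry of pluggable solvation backends. A backend is
# function(pep, config) -> kcal/mol.
.solvation_registry <- new.env(parent = emptyenv())

#' Register a solvation backend
#'
#' @param name Model identifier used in [solvation_config()].
#' @param fn Function of `(pep, config)` returning kcal/mol.
#' @export
register_solvation_model <- function(name, fn) {
  stopifnot(is.character(name), length(name) == 1, is.function(fn))
  assign(name, fn, envir = .solvation_registry)
  invisible(name)
}

solvation_models <- function() ls(.solvation_registry)

.sasa_solvation <- function(pep, config) {
  a <- sasa(pep, probe_radius = config$probe_radius,
            n_sphere_points = config$n_sphere_points)
  sum(pep$atoms$solvation_param * a)
}

#' Implicit solvation energy
#'
#' Dispatches to the configured solvation backend. The default `"sasa"`
#' model returns the SASA-weighted sum of atomic solvation parameters.
#'
#' @param pep A [peptide()].
#' @param config A [solvation_config()] (or an [energy_config()], whose
#'   solvation component is used).
#' @return Energy in kcal/mol.
#' @export
solvation_energy <- function(pep, config = solvation_config()) {
  if (inherits(config, "energy_config")) config <- config$solvation
  fn <- .solvation_registry[[config$model]]
  if (is.null(fn)) {
    stop("unknown solvation model '", config$model, "'; registered models: ",
         paste(solvation_models(), collapse = ", "), call. = FALSE)
  }
  fn(pep, config)
}

#' Total decomposed stability energy
#'
#' Computes the three-term stability estimate
#' `E = solvation + LJ + Coulomb` and returns the breakdown. Low values
#' indicate stable energetics; high values indicate destabilizing
#' interactions.
#'
#' @inheritParams lj_energy
#' @return An `energy_breakdown` list with elements `lj`, `coulomb`,
#'   `solvation` and `total` (all kcal/mol); `total` is exactly the sum
#'   of the three terms.
#' @export
total_energy <- function(pep, config = energy_config()) {
  pep <- with_nb_cache(pep, config)
  p <- attr(pep, "nb_cache")
  nb <- .nb_energy_cpp(peptide_coords(pep), p$i, p$j, p$sigma, p$epsilon,
                       p$qq, config$cutoff)
  solv <- solvation_energy(pep, config$solvation)
  structure(list(lj = nb$lj, coulomb = nb$coulomb, solvation = solv,
                 total = nb$lj + nb$coulomb + solv),
            class = "energy_breakdown")
}

#' @export
print.energy_breakdown <- function(x, ...) {
  cat(sprintf("LJ %12.3f  Coulomb %12.3f  Solvation %10.3f  Total %12.3f kcal/mol\n",
              x$lj, x$coulomb, x$solvation, x$total))
  invisible(x)
}

#' Stability change of a mutant relative to native
#'
#' `delta_e = E - E0` where `E0` is the total energy of the native
#' structure under the same configuration and relaxation protocol.
#' Positive values indicate decreased stability; negative values indicate
#' increased stability.
#'
#' @param mutant_total Total energy of the mutant, kcal/mol (or an
#'   `energy_breakdown`).
#' @param native_total Total energy of the native, kcal/mol (or an
#'   `energy_breakdown`).
#' @return Energy difference in kcal/mol.
#' @export
delta_e <- function(mutant_total, native_total) {
  if (inherits(mutant_total, "energy_breakdown")) mutant_total <- mutant_total$total
  if (inherits(native_total, "energy_breakdown")) native_total <- native_total$total
  mutant_total - native_total
}

#' Steepest-descent relaxation
#'
#' Relaxes steric clashes by steepest descent on the LJ + Coulomb
#' gradient with adaptive step halving. Solvation is held constant during
#' each line search and re-evaluated when a step is accepted; a step is
#' only accepted if the full three-term total does not increase, so the
#' total energy is non-increasing across accepted steps. Stops when the
#' largest gradient component drops below `force_tol` or after
#' `max_steps` accepted steps.
#'
#' @param pep A [peptide()].
#' @param config An [energy_config()].
#' @param max_steps Maximum accepted steps (default 200).
#' @param force_tol Convergence threshold on the maximum gradient
#'   component, kcal/(mol A) (default 0.1).
#' @param backbone_fixed If `TRUE` (default), N/CA/C/O atoms are frozen
#'   and only side-chain atoms move.
#' @param initial_step Initial maximum per-coordinate displacement, A.
#' @return The relaxed [peptide()]; attribute `minimize_log` holds a
#'   data.frame of accepted-step energies, attribute `converged` the
#'   convergence flag.
#' @export
minimize <- function(pep, config = energy_config(), max_steps = 200,
                     force_tol = 0.1, backbone_fixed = TRUE,
                     initial_step = 0.05) {
  pep <- with_nb_cache(pep, config)
  p <- attr(pep, "nb_cache")
  coords <- peptide_coords(pep)
  free <- if (backbone_fixed) {
    setdiff(seq_len(nrow(coords)), backbone_indices(pep))
  } else {
    seq_len(nrow(coords))
  }
  solv <- solvation_energy(pep, config$solvation)
  g <- .nb_gradient_cpp(coords, p$i, p$j, p$sigma, p$epsilon, p$qq,
                        config$cutoff)
  e_nb <- g$lj + g$coulomb
  if (!is.finite(e_nb) || e_nb > 1e20) {
    stop("energy diverges at start (steric clash too severe); ",
         "increase initial atom separation", call. = FALSE)
  }
  total <- e_nb + solv
  log_rows <- list(data.frame(step = 0L, lj = g$lj, coulomb = g$coulomb,
                              solvation = solv, total = total, alpha = NA_real_))
  alpha <- initial_step
  steps <- 0L
  converged <- FALSE
  while (steps < max_steps) {
    gmat <- g$gradient[free, , drop = FALSE]
    gmax <- max(abs(gmat))
    if (gmax < force_tol || length(free) == 0) {
      converged <- TRUE
      break
    }
    dir <- -gmat / gmax  # max per-coordinate displacement = alpha
    accepted <- FALSE
    for (h in 1:25) {
      trial <- coords
      trial[free, ] <- coords[free, ] + alpha * dir
      nb_t <- .nb_energy_cpp(trial, p$i, p$j, p$sigma, p$epsilon, p$qq,
                             config$cutoff)
      e_nb_t <- nb_t$lj + nb_t$coulomb
      if (is.finite(e_nb_t) && e_nb_t < e_nb) {
        pep_t <- set_peptide_coords(pep, trial)
        solv_t <- solvation_energy(pep_t, config$solvation)
        if (e_nb_t + solv_t <= total) {
          coords <- trial
          solv <- solv_t
          e_nb <- e_nb_t
          total <- e_nb_t + solv_t
          accepted <- TRUE
          break
        }
      }
      alpha <- alpha / 2
      if (alpha < 1e-7) break
    }
    if (!accepted) break
    steps <- steps + 1L
    g <- .nb_gradient_cpp(coords, p$i, p$j, p$sigma, p$epsilon, p$qq,
                          config$cutoff)
    log_rows[[steps + 1L]] <- data.frame(step = steps, lj = g$lj,
                                         coulomb = g$coulomb,
                                         solvation = solv, total = total,
                                         alpha = alpha)
    alpha <- min(alpha * 1.5, 0.5)
  }
  out <- set_peptide_coords(pep, coords)
  attr(out, "nb_cache") <- p
  attr(out, "minimize_log") <- do.call(rbind, log_rows)
  attr(out, "converged") <- converged
  out
}
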