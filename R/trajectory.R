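# RMSD/RMSF trajectory statistics with optimal rigid superposition, and
# a seeded synthetic-trajectory generator.

#' Construct a trajectory
#'
#' Time-ordered coordinate frames over a fixed atom set.
#'
#' @param coords Numeric array `n_frames x n_atoms x 3` (Angstrom), or a
#'   list of `n_atoms x 3` frame matrices.
#' @param times Frame times in ps; default 10 ps spacing.
#' @param atom_selection Optional integer indices (e.g. CA atoms) used by
#'   default in [rmsd_series()] and [rmsf()].
#' @param reference Optional reference frame (`n_atoms x 3`).
#' @return A `trajectory` object.
#' @export
trajectory <- function(coords, times = NULL, atom_selection = NULL,
                       reference = NULL) {
  if (is.list(coords)) {
    na <- nrow(coords[[1]])
    arr <- array(NA_real_, c(length(coords), na, 3))
    for (f in seq_along(coords)) {
      if (nrow(coords[[f]]) != na) stop("frames differ in atom count",
                                        call. = FALSE)
      arr[f, , ] <- coords[[f]]
    }
    coords <- arr
  }
  stopifnot(length(dim(coords)) == 3, dim(coords)[3] == 3)
  nf <- dim(coords)[1]
  if (is.null(times)) times <- 10 * (seq_len(nf) - 1)
  if (length(times) != nf || any(diff(times) <= 0)) {
    stop("times must be strictly increasing, one per frame", call. = FALSE)
  }
  if (!is.null(reference) && nrow(reference) != dim(coords)[2]) {
    stop("reference frame has wrong atom count", call. = FALSE)
  }
  structure(list(coords = coords, times = times,
                 atom_selection = atom_selection, reference = reference),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat("<trajectory> ", dim(x$coords)[1], " frames x ", dim(x$coords)[2],
      " atoms, ", x$times[1], "..", x$times[length(x$times)], " ps\n",
      sep = "")
  invisible(x)
}

# Optimal least-squares rotation (Kabsch, via 3x3 SVD with reflection
# correction) mapping centered mobile onto centered reference.
.kabsch_rotation <- function(mobile_c, reference_c) {
  h <- crossprod(mobile_c, reference_c)
  s <- svd(h)
  d <- sign(det(s$u %*% t(s$v)))
  s$u %*% diag(c(1, 1, d)) %*% t(s$v)
}

#' Root-mean-square deviation between two frames
#'
#' With `superpose = TRUE` (default) the mobile frame is first optimally
#' superposed on the reference by centroid alignment plus the
#' least-squares rotation (3x3 covariance SVD, reflection-corrected);
#' without superposition the raw RMS of per-atom deviations is returned.
#'
#' @param mobile,reference `n_atoms x 3` coordinate matrices with equal
#'   atom counts (>= 3 when superposing).
#' @param superpose Apply optimal rigid-body superposition first.
#' @return RMSD in Angstrom.
#' @export
rmsd <- function(mobile, reference, superpose = TRUE) {
  mobile <- as.matrix(mobile)
  reference <- as.matrix(reference)
  if (nrow(mobile) != nrow(reference)) {
    stop("mismatched atom counts: ", nrow(mobile), " vs ", nrow(reference),
         call. = FALSE)
  }
  if (superpose) {
    if (nrow(mobile) < 3) stop("superposition needs >= 3 atoms", call. = FALSE)
    mc <- colMeans(mobile)
    rc <- colMeans(reference)
    m0 <- sweep(mobile, 2, mc)
    r0 <- sweep(reference, 2, rc)
    mobile <- m0 %*% .kabsch_rotation(m0, r0)
    reference <- r0
  }
  sqrt(mean(rowSums((mobile - reference)^2)))
}

#' Per-frame RMSD series of a trajectory
#'
#' @param traj A [trajectory()].
#' @param reference Reference frame; default the trajectory's stored
#'   reference, else its first frame.
#' @param superpose Superpose each frame (default `TRUE`).
#' @param selection Atom indices; default the trajectory's selection,
#'   else all atoms.
#' @return data.frame with columns `time` and `rmsd`.
#' @export
rmsd_series <- function(traj, reference = NULL, superpose = TRUE,
                        selection = NULL) {
  sel <- selection %||% traj$atom_selection %||% seq_len(dim(traj$coords)[2])
  ref <- reference %||% traj$reference %||% traj$coords[1, , ]
  if (nrow(ref) == dim(traj$coords)[2]) {
    ref <- ref[sel, , drop = FALSE]
  } else if (nrow(ref) != length(sel)) {
    stop("reference must cover all atoms or exactly the selection",
         call. = FALSE)
  }
  vals <- vapply(seq_len(dim(traj$coords)[1]), function(f) {
    rmsd(traj$coords[f, sel, , drop = FALSE][1, , ], ref,
         superpose = superpose)
  }, numeric(1))
  data.frame(time = traj$times, rmsd = vals)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Per-atom root-mean-square fluctuation
#'
#' `RMSF_i = sqrt(mean_t |x_i(t) - ref_i|^2)` over the trajectory frames.
#' By default the reference is the per-atom time-averaged position (the
#' variance-minimizing choice); the first frame or a user-supplied frame
#' can be used instead. Low RMSF at a mutated position indicates the
#' absence of local residual instability.
#'
#' @param traj A [trajectory()] with >= 2 frames.
#' @param reference_mode One of `"mean"`, `"first"`, `"provided"`.
#' @param reference Reference frame when `reference_mode = "provided"`.
#' @param selection Atom indices; default the trajectory's selection,
#'   else all atoms.
#' @return Numeric vector of per-atom RMSF in Angstrom.
#' @export
rmsf <- function(traj, reference_mode = c("mean", "first", "provided"),
                 reference = NULL, selection = NULL) {
  reference_mode <- match.arg(reference_mode)
  if (dim(traj$coords)[1] < 2) stop("need >= 2 frames", call. = FALSE)
  sel <- selection %||% traj$atom_selection %||% seq_len(dim(traj$coords)[2])
  x <- traj$coords[, sel, , drop = FALSE]
  ref <- switch(reference_mode,
                mean = apply(x, c(2, 3), mean),
                first = x[1, , ],
                provided = {
                  if (is.null(reference)) {
                    stop("reference_mode = 'provided' needs a reference",
                         call. = FALSE)
                  }
                  if (nrow(reference) != length(sel)) {
                    stop("provided reference has wrong atom count: ",
                         nrow(reference), " vs ", length(sel), call. = FALSE)
                  }
                  as.matrix(reference)
                })
  dev2 <- sweep(x, c(2, 3), ref)^2
  sqrt(apply(dev2, 2, mean) * 3)  # mean over frames & axes, times 3 axes
}

#' Synthetic fluctuating trajectory
#'
#' Frames are the reference plus i.i.d. per-coordinate Gaussian noise of
#' standard deviation `sigma`, reproducible for a fixed seed; frame times
#' are spaced 10 ps apart. Stands in for molecular-dynamics production so
#' the trajectory statistics are testable without an MD engine. The
#' global RNG state is left untouched.
#'
#' @param reference `n_atoms x 3` reference frame.
#' @param sigma Per-coordinate noise standard deviation, Angstrom (>= 0).
#' @param n_frames Number of frames (>= 1).
#' @param seed Integer seed.
#' @return A [trajectory()] with the reference attached.
#' @export
synthetic_trajectory <- function(reference, sigma, n_frames, seed = 1) {
  stopifnot(sigma >= 0, n_frames >= 1)
  reference <- as.matrix(reference)
  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (is.null(old_seed)) {
      if (exists(".Random.seed", globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old_seed, envir = globalenv())
    }
  })
  set.seed(seed)
  na <- nrow(reference)
  coords <- array(NA_real_, c(n_frames, na, 3))
  for (f in seq_len(n_frames)) {
    coords[f, , ] <- reference + matrix(rnorm(na * 3, sd = sigma), na, 3)
  }
  trajectory(coords, times = 10 * (seq_len(n_frames) - 1),
             reference = reference)
}

#' CA-atom indices of a peptide
#'
#' @param pep A [peptide()].
#' @return Integer indices of the CA atoms, one per residue.
#' @export
ca_indices <- function(pep) which(pep$atoms$name == "CA")

#' Read / write trajectories as plain-text CSV
#'
#' The CSV layout is `frame, atom, x, y, z` with frames numbered from 1.
#'
#' @param traj A [trajectory()].
#' @param path File path.
#' @export
write_trajectory_csv <- function(traj, path) {
  nf <- dim(traj$coords)[1]
  na <- dim(traj$coords)[2]
  df <- data.frame(frame = rep(seq_len(nf), each = na),
                   atom = rep(seq_len(na), nf),
                   x = as.vector(t(traj$coords[, , 1])),
                   y = as.vector(t(traj$coords[, , 2])),
                   z = as.vector(t(traj$coords[, , 3])))
  write.table(df, path, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_trajectory_csv
#' @export
read_trajectory_csv <- function(path) {
  df <- read.table(path, sep = ",", header = TRUE)
  frames <- sort(unique(df$frame))
  atoms <- sort(unique(df$atom))
  coords <- array(NA_real_, c(length(frames), length(atoms), 3))
  for (f in seq_along(frames)) {
    sub <- df[df$frame == frames[f], ]
    sub <- sub[order(sub$atom), ]
    coords[f, , ] <- as.matrix(sub[, c("x", "y", "z")])
  }
  trajectory(coords)
}

#' Read a multi-model PDB file as a trajectory
#'
#' MODEL/ENDMDL records become frames; atom order follows the file.
#'
#' @param path PDB file with one or more MODEL blocks.
#' @return A [trajectory()].
#' @export
read_trajectory_pdb <- function(path) {
  pdb <- bio3d::read.pdb(path, multi = TRUE)
  xyz <- pdb$xyz
  nf <- nrow(xyz)
  na <- ncol(xyz) / 3
  coords <- array(NA_real_, c(nf, na, 3))
  for (f in seq_len(nf)) {
    coords[f, , ] <- matrix(xyz[f, ], ncol = 3, byrow = TRUE)
  }
  trajectory(coords)
}

#' Write RMSD or RMSF results as two-column TSV
#'
#' @param x data.frame (e.g. from [rmsd_series()]) or a named/numbered
#'   numeric vector (e.g. from [rmsf()]).
#' @param path Output file.
#' @param names Column names for vector input.
#' @export
write_trajectory_stat <- function(x, path, names = c("atom", "value")) {
  if (!is.data.frame(x)) {
    x <- data.frame(seq_along(x), as.numeric(x))
    colnames(x) <- names
  }
  write.table(x, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
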