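# Per-mode, per-residue descriptors: C-alpha fluctuation, deformation
# energy, mode collectivity, and sinusoidal mode-interpolated trajectories.

#' Construct a per-residue scalar profile
#'
#' Light container shared by fluctuation, deformation-energy and PCA
#' contribution tracks.
#'
#' @param values numeric, one scalar per residue.
#' @param labels data frame of bead labels (at least `resno`; usually the
#'   `labels` of a `calpha_model`).
#' @param units unit string (`"A^2"`, `"energy"`, `"1"` when normalized).
#' @param normalization `"raw"` or `"minmax"`.
#' @param provenance free text (e.g. `"mode 7 deformation energy"`).
#' @return object of class `residue_profile`.
#' @export
residue_profile <- function(values, labels, units = "",
                            normalization = c("raw", "minmax"),
                            provenance = "") {
  normalization <- match.arg(normalization)
  stopifnot(length(values) == nrow(labels), all(is.finite(values)))
  if (normalization == "minmax") {
    stopifnot(abs(min(values)) < 1e-12, abs(max(values) - 1) < 1e-12)
  }
  structure(list(values = as.numeric(values), labels = labels,
                 units = units, normalization = normalization,
                 provenance = provenance),
            class = "residue_profile")
}

#' @export
print.residue_profile <- function(x, ...) {
  cat("<residue_profile> ", length(x$values), " residues (",
      x$normalization, ", ", x$units, ") ", x$provenance, "\n", sep = "")
  invisible(x)
}

#' @export
as.data.frame.residue_profile <- function(x, ...) {
  data.frame(resno = x$labels$resno, resname = x$labels$resname,
             value = x$values, stringsAsFactors = FALSE)
}

#' C-alpha atomic fluctuation of each residue along one mode
#'
#' The mean-square displacement amplitude residue i contributes to mode m
#' with a unit eigenvector: f_i = (e_ix^2 + e_iy^2 + e_iz^2) / lambda_m,
#' so softer modes move residues more. Summed over all internal modes this
#' reproduces the diagonal of the Hessian pseudo-inverse.
#'
#' @param modes a `mode_set`.
#' @param mode_index 1-based over all modes (mode 7 = first internal mode
#'   of a generic structure).
#' @param labels bead labels (data frame); defaults to sequential indices.
#' @return `residue_profile` (raw, A^2 per unit thermal energy in model
#'   units).
#' @export
mode_fluctuation <- function(modes, mode_index, labels = NULL) {
  check_internal_mode(modes, mode_index)
  e <- xyz_mat(modes$vectors[, mode_index])
  f <- rowSums(e^2) / modes$values[mode_index]
  residue_profile(f, labels %||% default_labels(modes$n_beads),
                  units = "A^2", normalization = "raw",
                  provenance = paste("mode", mode_index, "fluctuation"))
}

default_labels <- function(n) {
  data.frame(resno = seq_len(n), resname = "ALA", chain = "A",
             stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Deformation energy of each residue along one mode
#'
#' The share of elastic energy stored locally when the structure is
#' displaced along the mode with unit amplitude: for each spring the
#' axis-projected pair energy 1/2 * k_ij * (rhat_ij . (u_i - u_j))^2 is
#' split equally between its two beads. High values mark residues that are
#' locally strained -- flexing -- even when their absolute displacement is
#' small, which is the hinge signature. Totals close exactly: the profile
#' sums to lambda_m / 2 for a unit eigenvector.
#'
#' A rigid-body mode yields the all-zero profile (flagged via the
#' provenance string), not an error.
#'
#' @param model `calpha_model` with force constants built.
#' @param modes `mode_set` from the model's Hessian.
#' @param mode_index 1-based mode index.
#' @return `residue_profile` (raw, model energy units).
#' @export
deformation_energy <- function(model, modes, mode_index) {
  stopifnot(!is.null(model$k))
  if (mode_index < 1 || mode_index > length(modes$values)) {
    stop("mode index ", mode_index, " out of range")
  }
  u <- xyz_mat(modes$vectors[, mode_index])
  d <- deformation_from_displacement(model, u)
  residue_profile(d, model$labels, units = "energy", normalization = "raw",
                  provenance = paste0("mode ", mode_index,
                                      " deformation energy",
                                      if (modes$rigid[mode_index]) " (rigid mode)" else ""))
}

#' Deformation energy of an arbitrary displacement field
#'
#' @param model `calpha_model` with force constants.
#' @param u N x 3 displacement matrix.
#' @return numeric vector, per-bead energy share.
#' @export
deformation_from_displacement <- function(model, u) {
  xyz <- model$xyz
  n <- nrow(xyz)
  d <- numeric(n)
  pairs <- which(upper.tri(model$k) & model$k > 0, arr.ind = TRUE)
  for (p in seq_len(nrow(pairs))) {
    i <- pairs[p, 1]; j <- pairs[p, 2]
    dv <- xyz[j, ] - xyz[i, ]
    rhat <- dv / sqrt(sum(dv^2))
    proj <- sum(rhat * (u[i, ] - u[j, ]))
    e_pair <- 0.5 * model$k[i, j] * proj^2
    d[i] <- d[i] + e_pair / 2
    d[j] <- d[j] + e_pair / 2
  }
  d
}

#' Degree of collectivity of a mode
#'
#' Entropy-based measure of how many residues participate in the motion:
#' kappa = (1/N) * exp(-sum p_i log p_i), with p_i the normalized per-bead
#' squared amplitude. kappa = 1 for a perfectly delocalized mode (all
#' beads moving with equal amplitude) and 1/N for a mode localized on a
#' single bead. Large functional interdomain motions have high
#' collectivity, which is why the most collective low-frequency mode is
#' the default analysis mode.
#'
#' @param modes a `mode_set`.
#' @param mode_index 1-based index of an internal mode.
#' @return scalar in (1/N, 1].
#' @export
collectivity <- function(modes, mode_index) {
  check_internal_mode(modes, mode_index)
  e <- xyz_mat(modes$vectors[, mode_index])
  a2 <- rowSums(e^2)
  p <- a2 / sum(a2)
  h <- -sum(ifelse(p > 0, p * log(p), 0))
  exp(h) / modes$n_beads
}

#' Trajectory container
#'
#' @param coords F x N x 3 array of C-alpha coordinates (angstrom).
#' @param phase numeric length F (radians along the mode period, or NA
#'   for imported trajectories).
#' @param reference reference frame index.
#' @param aligned whether frames have been rigid-body fitted.
#' @return object of class `trajectory`.
#' @export
new_trajectory <- function(coords, phase = rep(NA_real_, dim(coords)[1]),
                           reference = 1L, aligned = FALSE) {
  stopifnot(length(dim(coords)) == 3L, dim(coords)[3] == 3L,
            all(is.finite(coords)))
  structure(list(coords = coords, phase = phase,
                 reference = as.integer(reference), aligned = aligned),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat("<trajectory> ", dim(x$coords)[1], " frames x ", dim(x$coords)[2],
      " beads", if (x$aligned) ", aligned" else "", "\n", sep = "")
  invisible(x)
}

#' Intermediate conformations along a normal mode
#'
#' Generates one period of harmonic motion along mode m:
#' x(phi) = x0 + A * sin(phi) * e_m, with phases on a uniform grid over
#' \[0, 2*pi\] (endpoints included). Frame 1 (phase 0) is exactly the
#' reference. For a unit eigenvector the maximum C-alpha RMSD from the
#' reference equals A/sqrt(N), attained exactly whenever the grid contains
#' pi/2, i.e. whenever `n_frames - 1` is divisible by 4 (true for the
#' default 21).
#'
#' @param model `calpha_model` (reference coordinates).
#' @param modes `mode_set`.
#' @param mode_index internal mode to animate.
#' @param amplitude A in angstrom * sqrt(N); `NULL` picks A so the maximum
#'   RMSD excursion is `max_rmsd`.
#' @param n_frames frames over one period (>= 3; default 21).
#' @param max_rmsd target peak RMSD (angstrom) used when `amplitude` is
#'   `NULL`; default 2.0, large enough to strain marginal hydrogen bonds
#'   while staying in the harmonic regime.
#' @return a `trajectory` (unaligned by construction but already in the
#'   reference frame).
#' @export
mode_trajectory <- function(model, modes, mode_index, amplitude = NULL,
                            n_frames = 21L, max_rmsd = 2.0) {
  check_internal_mode(modes, mode_index)
  if (n_frames < 3L) stop("n_frames must be >= 3")
  n <- modes$n_beads
  if (is.null(amplitude)) amplitude <- max_rmsd * sqrt(n)
  if (amplitude < 0) stop("amplitude must be non-negative")
  e <- xyz_mat(modes$vectors[, mode_index])
  phases <- seq(0, 2 * pi, length.out = n_frames)
  coords <- array(NA_real_, dim = c(n_frames, n, 3L))
  for (f in seq_len(n_frames)) {
    coords[f, , ] <- model$xyz + amplitude * sin(phases[f]) * e
  }
  traj <- new_trajectory(coords, phase = phases, reference = 1L,
                         aligned = FALSE)
  traj$amplitude <- amplitude
  traj$mode_index <- mode_index
  traj
}
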