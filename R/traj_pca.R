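# Trajectory PCA: rigid-body superposition onto a reference frame and
# eigendecomposition of the coordinate covariance, with per-residue
# contribution profiles for the leading components.

#' Superpose trajectory frames onto a reference frame
#'
#' Least-squares rigid-body (rotation + translation) fit of every frame
#' onto the chosen reference frame, via bio3d's coordinate fitting. After
#' fitting, each frame's RMSD to the reference is minimal over rigid
#' motions.
#'
#' @param traj a `trajectory`.
#' @param reference reference frame index (default: the trajectory's
#'   stored reference, usually 1).
#' @return the trajectory with fitted coordinates and `aligned = TRUE`.
#' @export
superpose <- function(traj, reference = traj$reference) {
  stopifnot(inherits(traj, "trajectory"))
  nf <- dim(traj$coords)[1]
  n <- dim(traj$coords)[2]
  if (n < 3L) stop("need at least 3 beads to superpose")
  ref <- traj$coords[reference, , ]
  if (degenerate_geometry(ref)) {
    stop("reference frame is degenerate (collinear beads); cannot fit")
  }
  xyz <- t(vapply(seq_len(nf), function(f) as_xyz_vec(traj$coords[f, , ]),
                  numeric(3L * n)))
  fitted <- bio3d::fit.xyz(fixed = as_xyz_vec(ref), mobile = xyz,
                           fixed.inds = seq_len(3L * n),
                           mobile.inds = seq_len(3L * n))
  coords <- array(NA_real_, dim = dim(traj$coords))
  for (f in seq_len(nf)) coords[f, , ] <- xyz_mat(fitted[f, ])
  out <- traj
  out$coords <- coords
  out$reference <- as.integer(reference)
  out$aligned <- TRUE
  out
}

degenerate_geometry <- function(m) {
  c0 <- sweep(m, 2, colMeans(m))
  sv <- svd(c0, nu = 0, nv = 0)$d
  sv[2] < 1e-8 * max(sv[1], 1)
}

#' Principal component analysis of an aligned trajectory
#'
#' Eigendecomposition of the 3N x 3N sample covariance of bead
#' coordinates about the trajectory mean. Component vectors are unit
#' length, sign-fixed (largest-magnitude component positive), and ordered
#' by decreasing eigenvalue; the eigenvalue sum equals the total
#' coordinate variance (trace of the covariance).
#'
#' @param traj an aligned `trajectory` with at least 2 frames.
#' @param k number of components for which per-residue contribution
#'   profiles are precomputed (default 3).
#' @return object of class `pca_result`: `values` (eigenvalues, A^2,
#'   descending), `vectors` (3N x 3N, bead-major), `contributions` (N x k
#'   matrix, columns sum to 1), `total_variance`, `reference`.
#' @export
traj_pca <- function(traj, k = 3L) {
  stopifnot(inherits(traj, "trajectory"))
  if (!isTRUE(traj$aligned)) {
    stop("trajectory must be superposed first (see superpose())")
  }
  nf <- dim(traj$coords)[1]
  if (nf < 2L) stop("need at least 2 frames for PCA")
  n <- dim(traj$coords)[2]
  x <- t(vapply(seq_len(nf), function(f) as_xyz_vec(traj$coords[f, , ]),
                numeric(3L * n)))
  cv <- cov(x)
  eig <- eigen(cv, symmetric = TRUE)
  values <- pmax(eig$values, 0)  # clip eigen's negative round-off
  vectors <- eig$vectors
  for (m in seq_len(ncol(vectors))) {
    piv <- which.max(abs(vectors[, m]))
    if (vectors[piv, m] < 0) vectors[, m] <- -vectors[, m]
  }
  k <- min(k, ncol(vectors))
  contributions <- vapply(seq_len(k), function(p)
    pc_contribution_values(vectors[, p]), numeric(n))
  structure(
    list(values = values, vectors = vectors,
         contributions = matrix(contributions, nrow = n),
         k = k, total_variance = sum(diag(cv)),
         reference = traj$reference),
    class = "pca_result"
  )
}

#' @export
print.pca_result <- function(x, ...) {
  pct <- if (x$total_variance > 0) {
    100 * x$values[seq_len(x$k)] / x$total_variance
  } else rep(0, x$k)
  cat("<pca_result> total variance ", format(x$total_variance, digits = 4),
      " A^2; PC1..PC", x$k, ": ",
      paste(sprintf("%.1f%%", pct), collapse = ", "), "\n", sep = "")
  invisible(x)
}

pc_contribution_values <- function(v) {
  e <- xyz_mat(v)
  rowSums(e^2) / sum(e^2)
}

#' Per-residue contribution to one principal component
#'
#' The squared norm of residue i's 3-vector within the (unit) component
#' vector: each profile is non-negative and sums to 1, measuring how much
#' of the collective displacement that component assigns to each residue.
#'
#' @param result a `pca_result`.
#' @param pc component index (within the retained `k`).
#' @param labels optional bead labels.
#' @return `residue_profile` (raw; dimensionless fractions).
#' @export
residue_contribution <- function(result, pc, labels = NULL) {
  stopifnot(inherits(result, "pca_result"))
  if (pc < 1 || pc > result$k) {
    stop("pc index ", pc, " out of retained range 1..", result$k)
  }
  n <- nrow(result$contributions)
  residue_profile(result$contributions[, pc],
                  labels %||% default_labels(n), units = "1",
                  normalization = "raw",
                  provenance = paste("PC", pc, "contribution"))
}
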