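# Elastic network model: secondary-structure- and disulfide-aware pairwise
# force constants on the C-alpha beads, the 3N x 3N Hessian, and its
# eigendecomposition into a mode set.

#' Default elastic-network force-field parameters
#'
#' A distance-weighted C-alpha network with reinforced chain bonds,
#' helix 1-4 and beta-bridge contacts, and explicit disulfide springs.
#' Units are an arbitrary consistent energy/angstrom^2 scale: every
#' profile the pipeline derives is either normalized or compared within
#' one run, so only ratios between the constants matter.
#'
#' @param k_bond spring constant for chain neighbours (|i-j| = 1).
#' @param gamma_sse stiffening factor for helix 1-4 pairs (2 <= |i-j| <= 4
#'   inside one helix span) and beta-bridge pairs (both beads in sheet
#'   spans, closer than `r_bridge`).
#' @param c_dist scale of the distance-decaying generic constant
#'   k(r) = c_dist / r^6 for pairs within `r_cut`.
#' @param k_ss disulfide spring constant, applied regardless of distance.
#' @param r_cut generic interaction cutoff (angstrom).
#' @param r_bridge maximum C-alpha distance for a beta-bridge pair
#'   (angstrom).
#' @return named list of parameters.
#' @export
ff_params <- function(k_bond = 1000, gamma_sse = 5, c_dist = 1e4,
                      k_ss = 500, r_cut = 15, r_bridge = 5.5) {
  p <- list(k_bond = k_bond, gamma_sse = gamma_sse, c_dist = c_dist,
            k_ss = k_ss, r_cut = r_cut, r_bridge = r_bridge)
  bad <- names(p)[vapply(p, function(v) !is.numeric(v) || length(v) != 1L ||
                           !is.finite(v) || v <= 0, logical(1))]
  if (length(bad)) {
    stop("force-field parameters must be positive scalars: ",
         paste(bad, collapse = ", "))
  }
  p
}

#' Build pairwise force constants for a C-alpha model
#'
#' Rule set, in order of precedence for each unordered bead pair (i, j):
#' chain neighbours (|i-j| = 1, same chain) get `k_bond`; disulfide pairs
#' get `k_ss` regardless of distance; helix 1-4 pairs (2 <= |i-j| <= 4,
#' both beads within one helix span) and beta-bridge pairs (both beads in
#' sheet spans, r <= r_bridge) get `gamma_sse * c_dist / r^6`; every other
#' pair within `r_cut` gets `c_dist / r^6`; pairs beyond `r_cut` get 0.
#'
#' @param model a `calpha_model` from [extract_calpha()] (or a synthetic
#'   generator).
#' @param params force-field parameters from [ff_params()].
#' @return the model with `$k` set to the symmetric N x N force-constant
#'   matrix (zero diagonal) and `$params` recorded.
#' @export
build_force_constants <- function(model, params = ff_params()) {
  stopifnot(inherits(model, "calpha_model"))
  params <- do.call(ff_params, params[names(formals(ff_params))[
    names(formals(ff_params)) %in% names(params)]])
  xyz <- model$xyz
  n <- nrow(xyz)
  if (n < 2L) stop("need at least 2 beads")
  r <- as.matrix(dist(xyz))

  k <- matrix(0, n, n)
  within <- r <= params$r_cut & r > 0
  k[within] <- params$c_dist / r[within]^6

  # SSE stiffening
  seq_sep <- abs(outer(seq_len(n), seq_len(n), "-"))
  same_chain <- outer(model$labels$chain, model$labels$chain, "==")
  helix_pair <- matrix(FALSE, n, n)
  sp <- model$sse_spans
  if (!is.null(sp) && nrow(sp)) {
    for (s in which(sp$kind == "helix")) {
      inh <- model$labels$chain == sp$chain[s] &
        model$labels$resno >= sp$start[s] & model$labels$resno <= sp$end[s]
      helix_pair <- helix_pair | outer(inh, inh, "&")
    }
  }
  helix14 <- helix_pair & seq_sep >= 2 & seq_sep <= 4
  in_sheet <- !is.na(model$sse_kind) & model$sse_kind == "sheet"
  bridge <- outer(in_sheet, in_sheet, "&") & r <= params$r_bridge &
    seq_sep >= 2
  sse_pair <- (helix14 | bridge) & r > 0
  k[sse_pair] <- params$gamma_sse * params$c_dist / r[sse_pair]^6

  # disulfides override the distance rules
  if (!is.null(model$disulfide_beads) && nrow(model$disulfide_beads)) {
    for (p in seq_len(nrow(model$disulfide_beads))) {
      i <- model$disulfide_beads[p, 1]; j <- model$disulfide_beads[p, 2]
      k[i, j] <- k[j, i] <- params$k_ss
    }
  }

  # chain bonds take top precedence
  nb <- seq_sep == 1 & same_chain
  k[nb] <- params$k_bond
  diag(k) <- 0

  comp <- network_components(k)
  if (max(comp) > 1L) {
    sizes <- table(comp)
    stop("elastic network is disconnected: ", length(sizes),
         " components with sizes ", paste(sizes, collapse = ", "),
         "; increase r_cut or check the structure")
  }
  model$k <- k
  model$params <- params
  model
}

network_components <- function(k) {
  n <- nrow(k)
  comp <- rep(0L, n)
  cur <- 0L
  for (s in seq_len(n)) {
    if (comp[s]) next
    cur <- cur + 1L
    stack <- s
    while (length(stack)) {
      i <- stack[[length(stack)]]
      stack <- stack[-length(stack)]
      if (comp[i]) next
      comp[i] <- cur
      stack <- c(stack, which(k[i, ] > 0 & comp == 0L))
    }
  }
  comp
}

#' Build the 3N x 3N elastic-network Hessian
#'
#' Standard pairwise harmonic Hessian at the reference geometry: for each
#' pair with spring constant k_ij and unit inter-bead vector rhat, the
#' off-diagonal 3x3 block is -k_ij * rhat %o% rhat and diagonal blocks
#' accumulate the positive counterparts, so translations are exact null
#' vectors. Coordinate layout is bead-major (x1, y1, z1, x2, ...).
#'
#' @param model a `calpha_model` with force constants built.
#' @return symmetric 3N x 3N matrix.
#' @export
build_hessian <- function(model) {
  stopifnot(inherits(model, "calpha_model"), !is.null(model$k))
  xyz <- model$xyz
  n <- nrow(xyz)
  h <- matrix(0, 3 * n, 3 * n)
  idx <- function(i) (3 * (i - 1) + 1):(3 * i)
  pairs <- which(upper.tri(model$k) & model$k > 0, arr.ind = TRUE)
  for (p in seq_len(nrow(pairs))) {
    i <- pairs[p, 1]; j <- pairs[p, 2]
    dv <- xyz[j, ] - xyz[i, ]
    r <- sqrt(sum(dv^2))
    if (r < 1e-6) {
      stop("coincident beads ", i, " and ", j, " (r = ", format(r), " A)")
    }
    u <- dv / r
    blk <- model$k[i, j] * (u %o% u)
    h[idx(i), idx(j)] <- h[idx(i), idx(j)] - blk
    h[idx(j), idx(i)] <- h[idx(j), idx(i)] - blk
    h[idx(i), idx(i)] <- h[idx(i), idx(i)] + blk
    h[idx(j), idx(j)] <- h[idx(j), idx(j)] + blk
  }
  h
}

#' Elastic-network potential energy of a displaced conformation
#'
#' E = 1/2 * sum over pairs of k_ij * (|r_ij| - |r_ij^0|)^2, the full
#' anharmonic pair energy whose second-order expansion at the reference
#' is the Hessian of [build_hessian()].
#'
#' @param model a `calpha_model` with force constants.
#' @param xyz displaced N x 3 coordinates.
#' @return scalar energy (model units).
#' @export
enm_energy <- function(model, xyz) {
  stopifnot(!is.null(model$k))
  r0 <- as.matrix(dist(model$xyz))
  r1 <- as.matrix(dist(xyz))
  sum(model$k[upper.tri(model$k)] *
        (r1[upper.tri(r1)] - r0[upper.tri(r0)])^2) / 2
}

#' Solve the normal modes of an elastic-network Hessian
#'
#' Full symmetric eigendecomposition. Eigenvalues are returned ascending
#' and modes are numbered 1-based over all 3N modes, so that for a
#' connected generic structure the six null-frequency rigid-body modes are
#' modes 1-6 and the first internal mode is mode 7. Modes with eigenvalue
#' below `zero_tol * max(eigenvalue)` are flagged rigid. Eigenvector sign
#' is fixed so each mode's largest-magnitude component is positive.
#'
#' @param hessian symmetric 3N x 3N matrix from [build_hessian()].
#' @param zero_tol relative tolerance separating null-frequency modes
#'   (default 1e-9; true null modes sit many orders below, soft internal modes above).
#' @return an object of class `mode_set`: list with `values` (ascending
#'   eigenvalues), `vectors` (3N x 3N, unit columns, bead-major layout),
#'   `rigid` (logical per mode), `n_beads`, `frequencies` (sqrt of
#'   clamped eigenvalues, model units).
#' @export
compute_modes <- function(hessian, zero_tol = 1e-9) {
  stopifnot(is.matrix(hessian), nrow(hessian) == ncol(hessian))
  if (max(abs(hessian - t(hessian))) > 1e-8 * max(1, max(abs(hessian)))) {
    stop("hessian is not symmetric")
  }
  eig <- eigen((hessian + t(hessian)) / 2, symmetric = TRUE)
  ord <- order(eig$values)  # ascending
  values <- eig$values[ord]
  vectors <- eig$vectors[, ord, drop = FALSE]
  lam_max <- max(values)
  if (lam_max <= 0) stop("hessian has no positive eigenvalue")
  if (min(values) < -1e-8 * lam_max) {
    warning("hessian has a significantly negative eigenvalue: ",
            format(min(values)))
  }
  rigid <- values < zero_tol * lam_max
  if (sum(rigid) > 6L) {
    warning(sum(rigid), " near-null modes found (6 expected for a ",
            "connected generic 3D model); geometry may be degenerate")
  }
  # deterministic sign: largest-magnitude component positive
  for (m in seq_along(values)) {
    v <- vectors[, m]
    piv <- which.max(abs(v))
    if (v[piv] < 0) vectors[, m] <- -v
  }
  structure(
    list(values = values, vectors = vectors, rigid = rigid,
         n_beads = nrow(hessian) / 3L,
         frequencies = sqrt(pmax(values, 0)), zero_tol = zero_tol),
    class = "mode_set"
  )
}

#' @export
print.mode_set <- function(x, ...) {
  cat("<mode_set> ", length(x$values), " modes over ", x$n_beads,
      " beads; ", sum(x$rigid), " rigid; first internal mode: ",
      first_internal_mode(x), "\n", sep = "")
  invisible(x)
}

#' Index of the first non-rigid (internal) mode
#'
#' For a connected generic structure this is mode 7.
#'
#' @param modes a `mode_set`.
#' @return 1-based mode index.
#' @export
first_internal_mode <- function(modes) {
  stopifnot(inherits(modes, "mode_set"))
  which(!modes$rigid)[1]
}

check_internal_mode <- function(modes, mode_index) {
  if (mode_index < 1 || mode_index > length(modes$values)) {
    stop("mode index ", mode_index, " out of range")
  }
  if (modes$rigid[mode_index]) {
    stop("mode ", mode_index, " is a rigid-body (null-frequency) mode")
  }
  invisible(TRUE)
}

#' Export a mode table
#'
#' @param modes a `mode_set`.
#' @return data frame with mode index, eigenvalue, frequency (sqrt of the
#'   eigenvalue, model units) and rigid flag.
#' @export
mode_table <- function(modes) {
  data.frame(mode = seq_along(modes$values), eigenvalue = modes$values,
             frequency = modes$frequencies, rigid = modes$rigid)
}
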