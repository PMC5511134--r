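# Shared fixtures and independent oracles. Oracles are deliberately
# written as naive double loops / alternative algorithms so they stay
# independent of the implementation paths they check.

# a bare calpha_model from coordinates, bypassing PDB plumbing
bare_model <- function(xyz, chain = "A", sse_spans = NULL,
                       disulfide_beads = matrix(integer(), ncol = 2)) {
  n <- nrow(xyz)
  labels <- data.frame(resno = seq_len(n), resname = "GLY", chain = chain,
                       pdb_resno = seq_len(n), ins = "",
                       stringsAsFactors = FALSE)
  in_sse <- rep(FALSE, n)
  sse_kind <- rep(NA_character_, n)
  if (!is.null(sse_spans)) {
    for (s in seq_len(nrow(sse_spans))) {
      hit <- labels$resno >= sse_spans$start[s] &
        labels$resno <= sse_spans$end[s]
      in_sse[hit] <- TRUE
      sse_kind[hit] <- sse_spans$kind[s]
    }
  }
  structure(
    list(xyz = xyz, labels = labels, in_sse = in_sse, sse_kind = sse_kind,
         disulfide_beads = disulfide_beads, sse_spans = sse_spans,
         k = NULL, params = NULL, source = "test"),
    class = "calpha_model")
}

# random bead cloud with a minimum separation, chain-ordered
random_cloud <- function(n, seed, box = 12, min_sep = 3.0) {
  set.seed(seed)
  pts <- matrix(NA_real_, n, 3)
  i <- 1L
  while (i <= n) {
    cand <- runif(3, 0, box)
    if (i == 1L ||
        min(sqrt(rowSums(sweep(pts[seq_len(i - 1L), , drop = FALSE],
                               2, cand)^2))) >= min_sep) {
      pts[i, ] <- cand
      i <- i + 1L
    }
  }
  pts
}

# brute-force reimplementation of the force-constant rule set
oracle_force_constants <- function(model, p) {
  n <- nrow(model$xyz)
  k <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    r <- sqrt(sum((model$xyz[i, ] - model$xyz[j, ])^2))
    val <- 0
    if (r <= p$r_cut) val <- p$c_dist / r^6
    same_helix <- FALSE
    if (!is.null(model$sse_spans)) {
      for (s in seq_len(nrow(model$sse_spans))) {
        sp <- model$sse_spans[s, ]
        if (sp$kind == "helix" &&
            model$labels$resno[i] >= sp$start && model$labels$resno[i] <= sp$end &&
            model$labels$resno[j] >= sp$start && model$labels$resno[j] <= sp$end)
          same_helix <- TRUE
      }
    }
    sep <- abs(i - j)
    both_sheet <- isTRUE(model$sse_kind[i] == "sheet") &&
      isTRUE(model$sse_kind[j] == "sheet")
    if ((same_helix && sep >= 2 && sep <= 4) ||
        (both_sheet && sep >= 2 && r <= p$r_bridge)) {
      val <- p$gamma_sse * p$c_dist / r^6
    }
    if (nrow(model$disulfide_beads)) {
      for (d in seq_len(nrow(model$disulfide_beads))) {
        pr <- model$disulfide_beads[d, ]
        if (setequal(pr, c(i, j))) val <- p$k_ss
      }
    }
    if (sep == 1) val <- p$k_bond
    k[i, j] <- val
  }
  k
}

# central finite differences of the ENM energy surface
oracle_fd_hessian <- function(model, h = 1e-4) {
  n <- nrow(model$xyz)
  H <- matrix(0, 3 * n, 3 * n)
  perturb <- function(a, delta) {
    x <- model$xyz
    x[ceiling(a / 3), ((a - 1) %% 3) + 1] <-
      x[ceiling(a / 3), ((a - 1) %% 3) + 1] + delta
    x
  }
  for (a in seq_len(3 * n)) for (b in a:(3 * n)) {
    xpp <- perturb(a, h); xpp[ceiling(b / 3), ((b - 1) %% 3) + 1] <-
      xpp[ceiling(b / 3), ((b - 1) %% 3) + 1] + h
    xpm <- perturb(a, h); xpm[ceiling(b / 3), ((b - 1) %% 3) + 1] <-
      xpm[ceiling(b / 3), ((b - 1) %% 3) + 1] - h
    xmp <- perturb(a, -h); xmp[ceiling(b / 3), ((b - 1) %% 3) + 1] <-
      xmp[ceiling(b / 3), ((b - 1) %% 3) + 1] + h
    xmm <- perturb(a, -h); xmm[ceiling(b / 3), ((b - 1) %% 3) + 1] <-
      xmm[ceiling(b / 3), ((b - 1) %% 3) + 1] - h
    H[a, b] <- H[b, a] <-
      (enm_energy(model, xpp) - enm_energy(model, xpm) -
         enm_energy(model, xmp) + enm_energy(model, xmm)) / (4 * h^2)
  }
  H
}

# quaternion (Horn) absolute-orientation solution, an algorithm
# independent of the SVD-based fitting used by the package
oracle_quaternion_fit <- function(mobile, fixed) {
  cm <- colMeans(mobile); cf <- colMeans(fixed)
  a <- sweep(mobile, 2, cm); b <- sweep(fixed, 2, cf)
  M <- t(a) %*% b
  S <- matrix(0, 4, 4)
  S[1, 1] <- M[1, 1] + M[2, 2] + M[3, 3]
  S[1, 2] <- S[2, 1] <- M[2, 3] - M[3, 2]
  S[1, 3] <- S[3, 1] <- M[3, 1] - M[1, 3]
  S[1, 4] <- S[4, 1] <- M[1, 2] - M[2, 1]
  S[2, 2] <- M[1, 1] - M[2, 2] - M[3, 3]
  S[2, 3] <- S[3, 2] <- M[1, 2] + M[2, 1]
  S[2, 4] <- S[4, 2] <- M[3, 1] + M[1, 3]
  S[3, 3] <- -M[1, 1] + M[2, 2] - M[3, 3]
  S[3, 4] <- S[4, 3] <- M[2, 3] + M[3, 2]
  S[4, 4] <- -M[1, 1] - M[2, 2] + M[3, 3]
  q <- eigen(S, symmetric = TRUE)$vectors[, 1]
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  R <- matrix(c(
    w^2 + x^2 - y^2 - z^2, 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), w^2 - x^2 + y^2 - z^2, 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), w^2 - x^2 - y^2 + z^2),
    3, 3, byrow = TRUE)
  fitted <- sweep(a %*% t(R), 2, cf, "+")
  list(fitted = fitted, rmsd = sqrt(mean(rowSums((fitted - fixed)^2))))
}

# exhaustive region finder: scan every residue, merge by walking
oracle_regions <- function(qual, max_gap) {
  regions <- list()
  cur <- NULL
  gap <- 0L
  for (i in seq_along(qual)) {
    if (qual[i]) {
      if (is.null(cur)) cur <- c(i, i) else cur[2] <- i
      gap <- 0L
    } else if (!is.null(cur)) {
      gap <- gap + 1L
      if (gap > max_gap) {
        regions[[length(regions) + 1L]] <- cur
        cur <- NULL
        gap <- 0L
      }
    }
  }
  if (!is.null(cur)) regions[[length(regions) + 1L]] <- cur
  regions
}

# random rotation matrix (QR of a Gaussian matrix, det +1)
random_rotation <- function(seed) {
  set.seed(seed)
  q <- qr.Q(qr(matrix(rnorm(9), 3, 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

# the canonical two-domain study system used across tests
study_dumbbell <- function(seed = 7) {
  db <- make_dumbbell(24, 5, seed = seed, compaction = 0.6)
  model <- build_force_constants(extract_calpha(db$structure))
  modes <- compute_modes(build_hessian(model))
  list(db = db, model = model, modes = modes)
}
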