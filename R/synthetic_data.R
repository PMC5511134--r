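# Seeded synthetic generators: ideal alpha-helices, two-domain dumbbells
# with a known flexible linker (ground-truth hinge), and trajectories
# sampled along planted normal modes. Every generator is deterministic
# under a fixed seed, and emits objects that flow through the same code
# paths as parsed PDB structures.

#' Generate an ideal alpha-helix structure
#'
#' C-alpha atoms on an ideal alpha-helix (rise 1.5 A per residue, 100
#' degrees per residue, radius 2.3 A) plus backbone N, C and O at fixed
#' idealized cylindrical offsets, with optional isotropic Gaussian
#' coordinate noise. A single HELIX span covers all residues.
#'
#' @param n number of residues (>= 4).
#' @param noise Gaussian noise s.d. per coordinate (angstrom; default 0).
#' @param seed RNG seed (used only when `noise > 0`).
#' @return a `structure`.
#' @export
make_helix <- function(n, noise = 0, seed = 1L) {
  if (n < 4L) stop("need n >= 4 residues for a helix")
  # idealized backbone cylinder parameters: (radius, phase offset deg,
  # z offset) relative to each residue's C-alpha position on the helix
  geom <- list(
    CA = c(2.30, 0, 0),
    N = c(1.60, -28, -0.70),
    C = c(1.70, 26, 0.60),
    O = c(2.00, 23, 1.60)
  )
  rise <- 1.5; twist <- 100 * pi / 180
  rows <- list()
  for (i in seq_len(n)) {
    phi <- (i - 1) * twist
    for (nm in names(geom)) {
      g <- geom[[nm]]
      a <- phi + g[2] * pi / 180
      rows[[length(rows) + 1L]] <- data.frame(
        atom = nm, element = substr(nm, 1, 1), resname = "ALA",
        chain = "A", resno = i, ins = "",
        x = g[1] * cos(a), y = g[1] * sin(a), z = (i - 1) * rise + g[3],
        altloc = "", occupancy = 1, stringsAsFactors = FALSE)
    }
  }
  atoms <- do.call(rbind, rows)
  if (noise > 0) {
    set.seed(seed)
    atoms$x <- atoms$x + rnorm(nrow(atoms), 0, noise)
    atoms$y <- atoms$y + rnorm(nrow(atoms), 0, noise)
    atoms$z <- atoms$z + rnorm(nrow(atoms), 0, noise)
  }
  sse <- data.frame(kind = "helix", chain = "A", start = 1L, end = n,
                    stringsAsFactors = FALSE)
  dis <- data.frame(chain1 = character(), res1 = integer(),
                    chain2 = character(), res2 = integer(),
                    stringsAsFactors = FALSE)
  new_structure(atoms, sse, dis,
                source = sprintf("synthetic helix n=%d noise=%g seed=%d",
                                 n, noise, seed))
}

#' Generate a two-domain dumbbell with a known flexible linker
#'
#' Two compact globular C-alpha clusters joined by an extended zigzag
#' linker. Each domain is a set of jittered close-packed (fcc) lattice
#' points at protein-like density, chained by a greedy nearest-neighbour
#' path so consecutive beads stay near bonding distance; this makes the
#' domains internally stiff, so elastic strain under interdomain motion
#' concentrates in the linker. The linker is the ground-truth hinge: the
#' lowest internal elastic-network modes of this geometry are interdomain
#' bend/twist motions pivoting about it.
#'
#' @param n_domain residues per domain (>= 8).
#' @param n_linker linker residues (>= 2).
#' @param seed RNG seed (controls the lattice jitter).
#' @param jitter Gaussian displacement s.d. applied to lattice points
#'   (angstrom, default 0.3) so domains are irregular but still compact.
#' @param compaction ratio of the straight attachment-to-attachment
#'   distance to the linker contour length (default 0.6): smaller values
#'   bow the linker more and bring the domain surfaces closer together.
#' @param max_retries kept for interface stability; cluster construction
#'   is deterministic and does not retry.
#' @return list: `structure` (C-alpha-only `structure`), `linker_span`
#'   (integer residue numbers of the linker, ground truth).
#' @export
make_dumbbell <- function(n_domain, n_linker, seed = 1L, jitter = 0.3,
                          compaction = 0.6, max_retries = 50L) {
  if (n_domain < 8L) stop("need n_domain >= 8")
  if (n_linker < 2L) stop("need n_linker >= 2")
  set.seed(seed)
  step <- 3.8

  dom1 <- domain_cluster(n_domain, step, jitter)
  # chain dom1 so its path ends at the bead with the largest x
  # (the attachment point toward the linker)
  dom1 <- dom1[greedy_chain_path(dom1, start = which.max(dom1[, 1]))[n_domain:1], ]

  # The linker bows over the interdomain gap as a flattened arc, placing
  # the second domain close enough that the domain surfaces interact
  # through the distance-decaying springs. A straight single-strand
  # tether would leave torsion about the linker axis essentially free
  # (a near-zero internal mode), which no compact two-domain protein
  # shows; the arc plus interface contacts brace that torsion while the
  # interdomain bend stays the softest internal motion. A small
  # alternating z offset breaks the planarity of the arc.
  p1 <- dom1[n_domain, ]
  contour <- (n_linker + 1L) * step
  span <- compaction * contour
  bow <- 0.9 * sqrt(max(contour^2 / 4 - span^2 / 4, step^2))
  t_i <- seq_len(n_linker) / (n_linker + 1L)
  linker <- cbind(p1[1] + span * t_i,
                  p1[2] + bow * 4 * t_i * (1 - t_i),
                  p1[3] + 0.65 * (seq_len(n_linker) %% 2))
  linker <- linker + matrix(rnorm(3 * n_linker, 0, jitter / 2),
                            n_linker, 3)

  dom2 <- domain_cluster(n_domain, step, jitter)
  dom2 <- dom2[greedy_chain_path(dom2, start = which.min(dom2[, 1])), ]
  # place dom2 so its first chain bead continues from the linker end
  q <- c(p1[1] + span, p1[2], p1[3])
  dom2 <- sweep(dom2, 2, dom2[1, ] - q)

  xyz <- rbind(dom1, linker, dom2)
  d_cross <- min(as.matrix(dist(rbind(dom1, dom2)))[
    seq_len(n_domain), n_domain + seq_len(n_domain)])
  if (d_cross < 3.0) {
    stop("domain placement produced a clash (min cross-domain distance ",
         format(d_cross, digits = 3), " A); try another seed")
  }
  n <- nrow(xyz)
  atoms <- data.frame(
    atom = "CA", element = "C", resname = "GLY", chain = "A",
    resno = seq_len(n), ins = "", x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
    altloc = "", occupancy = 1, stringsAsFactors = FALSE)
  # the compact domains are annotated as structured (sheet) spans; the
  # linker is coil -- mirroring a folded two-domain protein, engaging the
  # beta-bridge stiffening inside the domains and leaving only the linker
  # exposed to the secondary-structure exclusion
  sse <- data.frame(
    kind = "sheet", chain = "A",
    start = c(1L, n_domain + n_linker + 1L),
    end = c(n_domain, 2L * n_domain + n_linker),
    stringsAsFactors = FALSE)
  struct <- new_structure(
    atoms, sse,
    data.frame(chain1 = character(), res1 = integer(),
               chain2 = character(), res2 = integer(),
               stringsAsFactors = FALSE),
    source = sprintf("synthetic dumbbell %dx2+%d seed=%d", n_domain,
                     n_linker, seed))
  list(structure = struct,
       linker_span = (n_domain + 1L):(n_domain + n_linker))
}

# n fcc lattice points (nearest-neighbour distance = step) closest to
# the origin, with seeded Gaussian jitter
domain_cluster <- function(n, step, jitter) {
  a <- step / sqrt(2)           # cubic cell edge for fcc spacing = step
  m <- ceiling((n * 2)^(1 / 3)) + 2L
  g <- expand.grid(i = -m:m, j = -m:m, k = -m:m)
  g <- g[(g$i + g$j + g$k) %% 2 == 0, ]   # fcc: even-parity sites
  pts <- as.matrix(g) * a
  ord <- order(rowSums(pts^2))
  pts <- pts[ord[seq_len(n)], , drop = FALSE]
  pts + matrix(rnorm(3 * n, 0, jitter), n, 3)
}

# order cluster points into a chain by repeatedly hopping to the nearest
# unvisited point, so consecutive beads stay near bonding distance
greedy_chain_path <- function(pts, start = 1L) {
  n <- nrow(pts)
  path <- integer(n)
  visited <- rep(FALSE, n)
  path[1] <- start
  visited[start] <- TRUE
  d <- as.matrix(dist(pts))
  for (i in 2:n) {
    prev <- path[i - 1]
    cand <- which(!visited)
    nxt <- cand[which.min(d[prev, cand])]
    path[i] <- nxt
    visited[nxt] <- TRUE
  }
  path
}

#' Sample a trajectory along planted normal modes
#'
#' Frame f = reference + sum_k a_kf * e_k with amplitudes
#' a_kf ~ N(0, sigma_k), independent across frames and modes, plus
#' optional isotropic coordinate noise. Stands in for a long MD ensemble
#' whose covariance is dominated by a small set of collective modes, so
#' PCA recovery can be tested against known ground truth.
#'
#' @param model `calpha_model` providing the reference coordinates.
#' @param modes `mode_set` of the model.
#' @param plant integer vector of planted (internal) mode indices.
#' @param sigma amplitude s.d. per planted mode (angstrom * sqrt(N));
#'   recycled to `length(plant)`.
#' @param n_frames number of frames (>= 2).
#' @param seed RNG seed.
#' @param noise isotropic per-coordinate Gaussian noise s.d. (default 0).
#' @return a `trajectory` (unaligned; every frame, including frame 1, is
#'   an independently sampled displacement of the reference).
#' @export
sample_trajectory <- function(model, modes, plant, sigma, n_frames = 500L,
                              seed = 1L, noise = 0) {
  stopifnot(inherits(model, "calpha_model"), inherits(modes, "mode_set"))
  if (n_frames < 2L) stop("need n_frames >= 2")
  if (any(modes$rigid[plant])) {
    stop("planted modes must be internal (non-rigid): ",
         paste(plant[modes$rigid[plant]], collapse = ", "))
  }
  sigma <- rep_len(sigma, length(plant))
  set.seed(seed)
  n <- nrow(model$xyz)
  coords <- array(NA_real_, dim = c(n_frames, n, 3L))
  evecs <- lapply(plant, function(m) xyz_mat(modes$vectors[, m]))
  for (f in seq_len(n_frames)) {
    x <- model$xyz
    for (k in seq_along(plant)) {
      x <- x + rnorm(1, 0, sigma[k]) * evecs[[k]]
    }
    if (noise > 0) x <- x + matrix(rnorm(3 * n, 0, noise), n, 3)
    coords[f, , ] <- x
  }
  new_trajectory(coords, reference = 1L, aligned = FALSE)
}
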