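# Per-residue mode descriptors and mode-interpolated trajectories

two_bead_modes <- function(k = 7) {
  m <- bare_model(rbind(c(0, 0, 0), c(3.8, 0, 0)))
  m <- build_force_constants(m, ff_params(k_bond = k))
  list(model = m, modes = compute_modes(build_hessian(m)))
}

test_that("the two-body stretch mode moves both beads equally", {
  tb <- two_bead_modes()
  mi <- first_internal_mode(tb$modes)
  f <- mode_fluctuation(tb$modes, mi)
  expect_equal(f$values[1], f$values[2], tolerance = 1e-12)
  expect_equal(sum(f$values), 1 / tb$modes$values[mi], tolerance = 1e-10)
})

test_that("fluctuation is invariant to eigenvector sign", {
  st <- study_dumbbell(seed = 2)
  mi <- first_internal_mode(st$modes)
  f1 <- mode_fluctuation(st$modes, mi)
  flipped <- st$modes
  flipped$vectors[, mi] <- -flipped$vectors[, mi]
  f2 <- mode_fluctuation(flipped, mi)
  expect_equal(f1$values, f2$values)
})

test_that("fluctuation of a rigid mode is refused", {
  st <- study_dumbbell(seed = 2)
  expect_error(mode_fluctuation(st$modes, 1), "rigid")
})

test_that("fluctuations summed over modes equal the pseudo-inverse diagonal", {
  m <- bare_model(random_cloud(8, seed = 17))
  m <- build_force_constants(m, ff_params(r_cut = 20))
  h <- build_hessian(m)
  ms <- compute_modes(h)
  total <- rowSums(vapply(which(!ms$rigid), function(k)
    mode_fluctuation(ms, k)$values, numeric(8)))
  pinv <- MASS::ginv(h)
  oracle <- vapply(1:8, function(i) sum(diag(pinv)[(3 * i - 2):(3 * i)]),
                   numeric(1))
  expect_equal(total, oracle, tolerance = 1e-6)
})

test_that("rigid-body displacement fields store no deformation energy", {
  m <- bare_model(random_cloud(7, seed = 23))
  m <- build_force_constants(m, ff_params(r_cut = 20))
  centred <- sweep(m$xyz, 2, colMeans(m$xyz))
  # infinitesimal rotation about z plus a translation
  u <- cbind(-centred[, 2], centred[, 1], 0) * 0.01 +
    matrix(rep(c(0.3, -0.1, 0.2), 7), 7, 3, byrow = TRUE)
  expect_lt(max(deformation_from_displacement(m, u)), 1e-10)
})

test_that("the two-body stretch splits k/2 of energy onto each bead", {
  tb <- two_bead_modes(k = 7)
  mi <- first_internal_mode(tb$modes)
  d <- deformation_energy(tb$model, tb$modes, mi)
  expect_equal(d$values, c(7 / 2, 7 / 2), tolerance = 1e-10)
  expect_equal(sum(d$values), tb$modes$values[mi] / 2, tolerance = 1e-12)
})

test_that("deformation energies sum to half the eigenvalue for every internal mode", {
  m <- bare_model(random_cloud(8, seed = 31))
  m <- build_force_constants(m, ff_params(r_cut = 20))
  ms <- compute_modes(build_hessian(m))
  for (k in which(!ms$rigid)) {
    d <- deformation_energy(m, ms, k)
    expect_equal(sum(d$values), ms$values[k] / 2,
                 tolerance = 1e-9 * ms$values[k])
  }
})

test_that("deformation of a rigid mode is the flagged all-zero profile", {
  st <- study_dumbbell(seed = 2)
  d <- deformation_energy(st$model, st$modes, 3)
  expect_lt(max(d$values), 1e-10)
  expect_match(d$provenance, "rigid")
})

fake_modes <- function(vectors, values = NULL) {
  n <- nrow(vectors) / 3
  structure(list(
    values = values %||% rep(1, ncol(vectors)), vectors = vectors,
    rigid = rep(FALSE, ncol(vectors)), n_beads = n,
    frequencies = sqrt(values %||% rep(1, ncol(vectors))), zero_tol = 0),
    class = "mode_set")
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("collectivity spans its analytic extremes", {
  n <- 12
  uniform <- matrix(rep(c(1, 0, 0), n) / sqrt(n), ncol = 1)
  expect_equal(collectivity(fake_modes(uniform), 1), 1, tolerance = 1e-12)
  localized <- matrix(0, 3 * n, 1); localized[1] <- 1
  expect_equal(collectivity(fake_modes(localized), 1), 1 / n,
               tolerance = 1e-12)
})

test_that("collectivity ignores eigenvector sign and bead order", {
  st <- study_dumbbell(seed = 2)
  mi <- first_internal_mode(st$modes)
  kap <- collectivity(st$modes, mi)
  expect_gt(kap, 1 / st$modes$n_beads)
  expect_lte(kap, 1)
  flipped <- st$modes
  flipped$vectors[, mi] <- -flipped$vectors[, mi]
  expect_equal(collectivity(flipped, mi), kap)
  # permute beads
  set.seed(1)
  perm <- sample(st$modes$n_beads)
  v <- matrix(st$modes$vectors[, mi], ncol = 3, byrow = TRUE)[perm, ]
  shuffled <- fake_modes(matrix(as.numeric(t(v)), ncol = 1))
  expect_equal(collectivity(shuffled, 1), kap, tolerance = 1e-12)
})

test_that("zero-amplitude trajectories stay at the reference", {
  st <- study_dumbbell(seed = 2)
  traj <- mode_trajectory(st$model, st$modes, 7, amplitude = 0,
                          n_frames = 5)
  for (f in 1:5) expect_equal(traj$coords[f, , ], st$model$xyz)
})

test_that("mode trajectories obey sinusoid symmetry and the RMSD closed form", {
  st <- study_dumbbell(seed = 2)
  n <- nrow(st$model$xyz)
  amp <- 13
  traj <- mode_trajectory(st$model, st$modes, 7, amplitude = amp,
                          n_frames = 21)
  expect_equal(traj$coords[1, , ], st$model$xyz)  # phase 0 = reference
  # phase pi/2 displacement is minus the phase 3pi/2 displacement
  i_q <- which.min(abs(traj$phase - pi / 2))
  i_3q <- which.min(abs(traj$phase - 3 * pi / 2))
  d_q <- traj$coords[i_q, , ] - st$model$xyz
  d_3q <- traj$coords[i_3q, , ] - st$model$xyz
  expect_equal(d_q, -d_3q, tolerance = 1e-9)
  rmsds <- apply(traj$coords, 1, function(fr)
    rmsd_plain(matrix(fr, n, 3), st$model$xyz))
  expect_equal(max(rmsds), amp / sqrt(n), tolerance = 1e-9)
})

test_that("profiles are invariant under global rotation of the structure", {
  xyz <- random_cloud(9, seed = 41)
  m1 <- build_force_constants(bare_model(xyz), ff_params(r_cut = 20))
  ms1 <- compute_modes(build_hessian(m1))
  rot <- random_rotation(3)
  m2 <- build_force_constants(bare_model(xyz %*% t(rot)),
                              ff_params(r_cut = 20))
  ms2 <- compute_modes(build_hessian(m2))
  mi <- first_internal_mode(ms1)
  expect_equal(mode_fluctuation(ms1, mi)$values,
               mode_fluctuation(ms2, mi)$values, tolerance = 1e-6)
  expect_equal(deformation_energy(m1, ms1, mi)$values,
               deformation_energy(m2, ms2, mi)$values, tolerance = 1e-6)
})
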