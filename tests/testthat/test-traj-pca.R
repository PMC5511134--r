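# Trajectory superposition and principal component analysis

test_that("a rotated+translated copy superposes back to zero RMSD", {
  xyz <- random_cloud(10, seed = 3)
  rot <- random_rotation(8)
  moved <- sweep(xyz %*% t(rot), 2, c(5, -3, 11), "+")
  coords <- array(NA_real_, dim = c(2, 10, 3))
  coords[1, , ] <- xyz; coords[2, , ] <- moved
  fit <- superpose(new_trajectory(coords))
  expect_lt(rmsd_plain(fit$coords[2, , ], xyz), 1e-9)
  expect_true(fit$aligned)
})

test_that("fitted RMSD matches an independent quaternion solution", {
  set.seed(12)
  xyz <- random_cloud(12, seed = 31)
  nf <- 6L
  coords <- array(NA_real_, dim = c(nf, 12, 3))
  coords[1, , ] <- xyz
  for (f in 2:nf) {
    coords[f, , ] <- sweep(xyz + matrix(rnorm(36, 0, 0.8), 12, 3) %*%
                             t(random_rotation(f)), 2, rnorm(3, 0, 4), "+")
  }
  fit <- superpose(new_trajectory(coords))
  for (f in 2:nf) {
    want <- oracle_quaternion_fit(coords[f, , ], xyz)$rmsd
    expect_equal(rmsd_plain(fit$coords[f, , ], xyz), want,
                 tolerance = 1e-9)
  }
})

test_that("superposition is idempotent", {
  st <- study_dumbbell(seed = 3)
  traj <- sample_trajectory(st$model, st$modes, plant = 7, sigma = 4,
                            n_frames = 20, seed = 5)
  fit1 <- superpose(traj)
  fit2 <- superpose(fit1)
  expect_equal(fit1$coords, fit2$coords, tolerance = 1e-9)
})

test_that("degenerate (collinear) references are refused", {
  coords <- array(rep(cbind(1:5 * 3.8, 0, 0), each = 2),
                  dim = c(2, 5, 3))
  for (f in 1:2) coords[f, , ] <- cbind(1:5 * 3.8, 0, 0)
  expect_error(superpose(new_trajectory(coords)), "degenerate")
})

test_that("PCA of identical frames yields all-zero eigenvalues", {
  xyz <- random_cloud(8, seed = 2)
  coords <- array(NA_real_, dim = c(5, 8, 3))
  for (f in 1:5) coords[f, , ] <- xyz
  traj <- superpose(new_trajectory(coords))
  res <- traj_pca(traj)
  expect_lt(max(res$values), 1e-10)
})

test_that("PCA recovers a planted mode direction and variance", {
  st <- study_dumbbell(seed = 6)
  mi <- first_internal_mode(st$modes)
  sigma <- 3
  traj <- sample_trajectory(st$model, st$modes, plant = mi,
                            sigma = sigma, n_frames = 500, seed = 11)
  res <- traj_pca(superpose(traj))
  planted <- st$modes$vectors[, mi]
  cosine <- abs(sum(res$vectors[, 1] * planted))
  expect_gt(cosine, 0.99)
  expect_lt(abs(res$values[1] - sigma^2) / sigma^2, 0.15)
})

test_that("eigenvalues sum to the trace of the coordinate covariance", {
  st <- study_dumbbell(seed = 6)
  traj <- sample_trajectory(st$model, st$modes, plant = c(7, 8),
                            sigma = c(3, 2), n_frames = 60, seed = 2)
  fit <- superpose(traj)
  res <- traj_pca(fit)
  n <- dim(fit$coords)[2]
  x <- t(apply(fit$coords, 1, function(fr) as.numeric(t(fr))))
  expect_equal(sum(res$values), sum(diag(cov(x))), tolerance = 1e-8)
  expect_equal(res$total_variance, sum(res$values), tolerance = 1e-8)
})

test_that("PCA eigenvalues agree with an independent implementation", {
  st <- study_dumbbell(seed = 6)
  traj <- sample_trajectory(st$model, st$modes, plant = 7, sigma = 3,
                            n_frames = 80, seed = 4)
  fit <- superpose(traj)
  res <- traj_pca(fit)
  x <- t(apply(fit$coords, 1, function(fr) as.numeric(t(fr))))
  ref <- bio3d::pca.xyz(x)
  expect_equal(res$values[1:10], ref$L[1:10], tolerance = 1e-8)
})

test_that("residue contributions are simplex-valued and localize correctly", {
  n <- 10
  v <- numeric(3 * n); v[4:6] <- c(0.6, 0.8, 0)  # all on residue 2
  fake <- structure(list(values = 1, vectors = matrix(v / 1, ncol = 1),
                         contributions = NULL, k = 1, total_variance = 1,
                         reference = 1L), class = "pca_result")
  fake$contributions <- matrix(hingescan:::pc_contribution_values(v),
                               ncol = 1)
  prof <- residue_contribution(fake, 1)
  expect_equal(sum(prof$values), 1, tolerance = 1e-10)
  expect_equal(prof$values[2], 1)
  uniform <- rep(1 / sqrt(3 * n), 3 * n)
  expect_equal(hingescan:::pc_contribution_values(uniform),
               rep(1 / n, n), tolerance = 1e-12)
})

test_that("a planted two-residue motion dominates the PC1 contributions", {
  m <- bare_model(random_cloud(12, seed = 51))
  m <- build_force_constants(m, ff_params(r_cut = 25))
  ms <- compute_modes(build_hessian(m))
  # a pure internal two-residue motion: antisymmetric stretch of beads 4
  # and 9 along their separation vector (zero net translation and torque,
  # so rigid-body fitting cannot redistribute it onto other beads)
  d49 <- m$xyz[9, ] - m$xyz[4, ]
  d49 <- d49 / sqrt(sum(d49^2))
  v <- numeric(36)
  v[c(10, 11, 12)] <- d49 / sqrt(2)
  v[c(25, 26, 27)] <- -d49 / sqrt(2)
  set.seed(13)
  coords <- array(NA_real_, dim = c(500, 12, 3))
  for (f in 1:500) {
    coords[f, , ] <- m$xyz + rnorm(1, 0, 2) *
      matrix(v, ncol = 3, byrow = TRUE)
  }
  res <- traj_pca(superpose(new_trajectory(coords)))
  contrib <- residue_contribution(res, 1)$values
  expect_gt(contrib[4] + contrib[9], 0.95)
})

test_that("contributions are invariant to a global pre-rotation of frames", {
  st <- study_dumbbell(seed = 6)
  traj <- sample_trajectory(st$model, st$modes, plant = 7, sigma = 3,
                            n_frames = 120, seed = 9)
  res1 <- traj_pca(superpose(traj))
  rot <- random_rotation(17)
  rotated <- traj
  for (f in seq_len(dim(traj$coords)[1])) {
    rotated$coords[f, , ] <- traj$coords[f, , ] %*% t(rot)
  }
  res2 <- traj_pca(superpose(rotated))
  expect_equal(res2$contributions[, 1], res1$contributions[, 1],
               tolerance = 1e-6)
})

test_that("PCA of a mode-sampled ensemble recovers the planted subspace", {
  st <- study_dumbbell(seed = 6)
  plant <- c(7L, 8L)
  traj <- sample_trajectory(st$model, st$modes, plant = plant,
                            sigma = c(4, 2.5), n_frames = 1000, seed = 21)
  res <- traj_pca(superpose(traj))
  # principal angles between span(PC1,PC2) and span(planted modes)
  a <- qr.Q(qr(res$vectors[, 1:2]))
  b <- qr.Q(qr(st$modes$vectors[, plant]))
  angles <- acos(pmin(1, svd(t(a) %*% b)$d)) * 180 / pi
  expect_lt(max(angles), 10)
})
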