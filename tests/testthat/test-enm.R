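# Elastic-network force constants, Hessian construction and mode solution

test_that("chain neighbours get the bond constant", {
  m <- bare_model(rbind(c(0, 0, 0), c(3.8, 0, 0)))
  m <- build_force_constants(m, ff_params())
  expect_equal(m$k[1, 2], 1000)
  expect_equal(m$k[2, 1], 1000)
  expect_equal(diag(m$k), c(0, 0))
})

test_that("disulfide pairs take k_ss regardless of the distance rule", {
  xyz <- rbind(c(0, 0, 0), c(3.8, 0, 0), c(3.8, 3.8, 0), c(0, 5.3, 0))
  m <- bare_model(xyz, disulfide_beads = cbind(1L, 4L))
  m <- build_force_constants(m, ff_params(r_cut = 10))
  expect_equal(m$k[1, 4], 500)  # 1-4 distance 5.3 A: k_ss, not c/r^6
})

test_that("force constants match a brute-force double-loop oracle", {
  for (seed in c(2, 5)) {
    xyz <- random_cloud(10, seed = seed)
    sse <- data.frame(kind = c("helix", "sheet"), chain = "A",
                      start = c(2L, 8L), end = c(6L, 10L),
                      stringsAsFactors = FALSE)
    m <- bare_model(xyz, sse_spans = sse,
                    disulfide_beads = cbind(1L, 9L))
    p <- ff_params(r_cut = 12)
    m <- build_force_constants(m, p)
    expect_equal(m$k, oracle_force_constants(m, p), tolerance = 1e-12)
    expect_true(isSymmetric(m$k))
  }
})

test_that("two beads joined by one spring give eigenvalue 2k on the axis", {
  m <- bare_model(rbind(c(0, 0, 0), c(3.8, 0, 0)))
  m <- build_force_constants(m, ff_params(k_bond = 7))
  h <- build_hessian(m)
  ev <- eigen(h, symmetric = TRUE)$values
  expect_equal(max(ev), 14, tolerance = 1e-10)
  expect_equal(sum(ev > 1e-9), 1L)  # single internal mode
  # its eigenvector is the antisymmetric axial stretch
  vec <- eigen(h, symmetric = TRUE)$vectors[, 1]
  expect_equal(abs(vec), c(1, 0, 0, 1, 0, 0) / sqrt(2), tolerance = 1e-10)
})

test_that("rigid translations are exact null vectors of the Hessian", {
  m <- bare_model(random_cloud(8, seed = 11))
  m <- build_force_constants(m, ff_params(r_cut = 20))
  h <- build_hessian(m)
  for (t_dir in list(c(1, 0, 0), c(0, 1, 0), c(1, -2, 3))) {
    tt <- rep(t_dir, 8)
    expect_lt(max(abs(h %*% tt)), 1e-9)
  }
})

test_that("the analytic Hessian matches finite differences of the energy", {
  m <- bare_model(random_cloud(5, seed = 4))
  m <- build_force_constants(m, ff_params(r_cut = 20))
  h <- build_hessian(m)
  h_fd <- oracle_fd_hessian(m)
  expect_lt(max(abs(h - h_fd)), 1e-5)
})

test_that("coincident beads are rejected by name", {
  m <- bare_model(rbind(c(0, 0, 0), c(0, 0, 0), c(4, 0, 0)))
  m$k <- matrix(1, 3, 3); diag(m$k) <- 0
  expect_error(build_hessian(m), "coincident beads 1 and 2")
})

test_that("a generic folded structure has exactly six null-frequency modes", {
  st <- study_dumbbell(seed = 5)
  expect_equal(sum(st$modes$rigid), 6L)
  expect_equal(first_internal_mode(st$modes), 7L)
  expect_true(all(st$modes$values[!st$modes$rigid] > 0))
})

test_that("collinear beads have more than six near-zero modes", {
  xyz <- cbind(seq(0, 7.6, by = 3.8), 0, 0)
  m <- bare_model(xyz)
  m <- build_force_constants(m, ff_params())
  ms <- suppressWarnings(compute_modes(build_hessian(m)))
  expect_gt(sum(ms$rigid), 6L)
})

test_that("eigenvectors are orthonormal and satisfy the eigen equation", {
  m <- bare_model(random_cloud(9, seed = 8))
  m <- build_force_constants(m, ff_params(r_cut = 20))
  h <- build_hessian(m)
  ms <- compute_modes(h)
  g <- t(ms$vectors) %*% ms$vectors
  expect_lt(max(abs(g - diag(nrow(g)))), 1e-8)
  resid <- h %*% ms$vectors - ms$vectors %*% diag(ms$values)
  expect_lt(max(abs(resid)), 1e-8)
  expect_false(is.unsorted(ms$values))
})

test_that("quadratic form energy equals the pairwise spring sum", {
  m <- bare_model(random_cloud(10, seed = 13))
  m <- build_force_constants(m, ff_params(r_cut = 20))
  h <- build_hessian(m)
  set.seed(1)
  for (rep in 1:5) {
    u <- matrix(rnorm(30, 0, 0.05), 10, 3)
    quad <- 0.5 * drop(t(as.numeric(t(u))) %*% h %*% as.numeric(t(u)))
    pair_sum <- sum(deformation_from_displacement(m, u))
    expect_equal(quad, pair_sum, tolerance = 1e-8)
  }
})

test_that("rotating the structure rotates modes but not eigenvalues", {
  xyz <- random_cloud(8, seed = 21)
  m1 <- build_force_constants(bare_model(xyz), ff_params(r_cut = 20))
  ms1 <- compute_modes(build_hessian(m1))
  rot <- random_rotation(6)
  m2 <- build_force_constants(bare_model(xyz %*% t(rot)),
                              ff_params(r_cut = 20))
  ms2 <- compute_modes(build_hessian(m2))
  expect_equal(ms1$values, ms2$values, tolerance = 1e-8)
})

test_that("disconnected networks are refused with component sizes", {
  xyz <- rbind(c(0, 0, 0), c(3.8, 0, 0), c(100, 0, 0), c(103.8, 0, 0))
  m <- bare_model(xyz)
  m$labels$chain <- c("A", "A", "B", "B")  # break the chain bond 2-3
  expect_error(build_force_constants(m, ff_params(r_cut = 15)),
               "disconnected")
})

test_that("mode fluctuations agree with an independent ENM implementation", {
  # bio3d's calpha force field is parameterized differently, but total
  # C-alpha fluctuation profiles of the same structure must agree closely
  hx <- make_helix(40, noise = 0.3, seed = 3)
  m <- build_force_constants(extract_calpha(hx))
  ms <- compute_modes(build_hessian(m))
  mine <- rowSums(vapply(which(!ms$rigid), function(k)
    mode_fluctuation(ms, k)$values, numeric(ms$n_beads)))
  f <- withr::local_tempfile(fileext = ".pdb")
  write_pdb(hx, f)
  nm <- suppressWarnings(bio3d::nma(bio3d::read.pdb(f, verbose = FALSE),
                                    ff = "calpha", mass = FALSE))
  expect_equal(sum(nm$L < 1e-9 * max(nm$L)), 6L)
  expect_gt(cor(mine, nm$fluctuations), 0.9)
})
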