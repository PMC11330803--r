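# Small synthetic DVF stacks with known structure, built directly on an
# 8^3 grid (no phantom involved).
toy_dvf <- function(vec, dims = c(8L, 8L, 8L), phase = NA_integer_) {
  dvf_volume(array(vec, c(dims, 3L)), spacing = c(4, 4, 4), phase = phase)
}

test_that("PCA recovers an exact low-rank stack and round-trips at full rank", {
  n <- 3 * 8^3
  set.seed(10)
  base <- rnorm(n); m1 <- rnorm(n); m2 <- rnorm(n)
  dvfs <- lapply(1:9, function(i)
    toy_dvf(base + sin(i) * m1 + cos(2 * i) * m2))
  model <- fit_pca(dvfs, k = 2)
  for (i in c(1, 5, 9)) {
    q <- project_dvf(model, dvfs[[i]])
    rec <- synthesize_dvf(model, q)
    expect_lt(max(abs(dvf_as_vector(rec) - dvf_as_vector(dvfs[[i]]))) /
                max(abs(dvf_as_vector(dvfs[[i]]))), 1e-8)
  }
  # general-position stack, k = rank: completeness
  set.seed(11)
  dvfs2 <- lapply(1:6, function(i) toy_dvf(rnorm(n)))
  m2f <- fit_pca(dvfs2, k = 5)
  expect_equal(m2f$k, 5L)
  for (d in dvfs2) {
    rec <- synthesize_dvf(m2f, project_dvf(m2f, d))
    expect_lt(max(abs(dvf_as_vector(rec) - dvf_as_vector(d))), 1e-8)
  }
  expect_warning(fit_pca(dvfs2, k = 10), "clamped")
  expect_error(fit_pca(dvfs2[1], k = 1), "at least 2")
})

test_that("eigenvectors are orthonormal and ratios non-increasing", {
  model <- small_pca()
  G <- crossprod(model$basis)
  expect_lt(max(abs(G - diag(ncol(G)))), 1e-8)
  expect_true(all(diff(model$explained_ratios) <= 1e-12))
  expect_equal(sum(model$explained_ratios), 1, tolerance = 1e-12)
})

test_that("information curve matches constructed spectra and closes at 100%", {
  n <- 3 * 8^3
  # four orthogonal equal-norm modes around a common mean, +/- pairs so the
  # mean is the base vector and each mode carries equal variance
  Q <- qr.Q(qr(matrix(rnorm(n * 4), n, 4)))
  dvfs <- list()
  for (j in 1:4) {
    dvfs[[2 * j - 1]] <- toy_dvf(Q[, j])
    dvfs[[2 * j]] <- toy_dvf(-Q[, j])
  }
  model <- fit_pca(dvfs, k = 4)
  ic <- information_curve(model)
  expect_equal(ic$cumulative_percent, c(25, 50, 75, 100), tolerance = 1e-8)
  expect_equal(ic$increment_percent, rep(25, 4), tolerance = 1e-8)
  # one dominant mode
  set.seed(12)
  dom <- lapply(1:6, function(i) toy_dvf(10 * i * Q[, 1] + 0.05 * rnorm(n)))
  icd <- information_curve(fit_pca(dom, k = 2))
  expect_gte(icd$cumulative_percent[1], 99)
  expect_equal(utils::tail(icd$cumulative_percent, 1), 100, tolerance = 1e-6)
  expect_true(all(diff(icd$cumulative_percent) >= -1e-9))
})

test_that("information curve equals a dense eigendecomposition oracle", {
  fourd <- small_4dct()
  X <- vapply(fourd$dvfs[-1], dvf_as_vector,
              numeric(3 * prod(small_spec()$grid_dims)))
  Xc <- X - rowMeans(X)
  lam <- eigen(crossprod(Xc), symmetric = TRUE)$values  # dense Gram oracle
  lam <- lam[lam > max(lam) * 1e-10]
  oracle <- 100 * cumsum(lam) / sum(lam)
  ic <- information_curve(small_pca())
  expect_equal(ic$cumulative_percent, oracle, tolerance = 1e-8)
})

test_that("projection is least-squares optimal and synthesis linear", {
  model <- small_pca()
  mean_dvf <- dvf_volume(array(model$mean_dvf, c(model$grid$dims, 3L)),
                         model$grid$spacing)
  expect_equal(project_dvf(model, mean_dvf), rep(0, 3), tolerance = 1e-8,
               ignore_attr = TRUE)
  p1 <- dvf_volume(array(model$mean_dvf + 5 * model$basis[, 1],
                         c(model$grid$dims, 3L)), model$grid$spacing)
  expect_equal(project_dvf(model, p1), c(5, 0, 0), tolerance = 1e-6,
               ignore_attr = TRUE)
  # dense normal-equations oracle on a random field
  set.seed(13)
  rnd <- dvf_volume(array(rnorm(3 * prod(model$grid$dims)),
                          c(model$grid$dims, 3L)), model$grid$spacing)
  Bk <- model$basis[, 1:model$k]
  q_ls <- solve(crossprod(Bk), crossprod(Bk, dvf_as_vector(rnd) - model$mean_dvf))
  expect_equal(project_dvf(model, rnd), drop(q_ls), tolerance = 1e-6,
               ignore_attr = TRUE)
  # linearity of synthesis
  q <- c(3, -2, 1)
  s0 <- dvf_as_vector(synthesize_dvf(model, 0 * q))
  s1 <- dvf_as_vector(synthesize_dvf(model, q))
  s2 <- dvf_as_vector(synthesize_dvf(model, 2 * q))
  expect_equal(s2 - s1, s1 - s0, tolerance = 1e-8)
  expect_equal(s0, model$mean_dvf, tolerance = 1e-12)
  expect_error(synthesize_dvf(model, c(1, 2)), "length")
})

test_that("truncation error is non-increasing in k", {
  fourd <- small_4dct()
  X <- vapply(fourd$dvfs[-1], dvf_as_vector,
              numeric(3 * prod(small_spec()$grid_dims)))
  model <- fit_pca(fourd$dvfs[-1], k = 3)
  errs <- vapply(1:8, function(k) {
    B <- model$basis[, 1:k, drop = FALSE]
    Xc <- X - model$mean_dvf
    sqrt(sum((Xc - B %*% crossprod(B, Xc))^2))
  }, numeric(1))
  expect_true(all(diff(errs) <= 1e-8))
})

test_that("coefficient sampling respects expanded bounds and reproduces", {
  model <- small_pca()
  phases <- small_phase_coeffs()
  q0 <- sample_coefficients(model, phases, n_samples = 500, expansion = 0,
                            seed = 5)
  lo <- apply(phases, 2, min); hi <- apply(phases, 2, max)
  for (j in 1:3) {
    expect_true(all(q0[, j] >= lo[j] & q0[, j] <= hi[j]))
  }
  q1 <- sample_coefficients(model, phases, n_samples = 900, expansion = 0.15,
                            seed = 5)
  expect_equal(dim(q1), c(900L, 3L))
  expect_identical(q1, sample_coefficients(model, phases, n_samples = 900,
                                           expansion = 0.15, seed = 5))
  R <- hi - lo
  for (j in 1:3)
    expect_true(all(q1[, j] >= lo[j] - 0.15 * R[j] - 1e-9 &
                    q1[, j] <= hi[j] + 0.15 * R[j] + 1e-9))
  # Monte-Carlo convergence of the empirical support to the expanded bounds
  qm <- sample_coefficients(model, phases, n_samples = 1e5, expansion = 0.15,
                            seed = 6)
  for (j in 1:3) {
    expect_lt(abs(min(qm[, j]) - (lo[j] - 0.15 * R[j])), 0.01 * R[j])
    expect_lt(abs(max(qm[, j]) - (hi[j] + 0.15 * R[j])), 0.01 * R[j])
  }
  flat <- matrix(rep(phases[1, ], 4), 4, byrow = TRUE)
  expect_error(sample_coefficients(model, flat), "degenerate")
})

test_that("warping reproduces identities, shifts and ramps", {
  set.seed(14)
  vals <- array(runif(16^3), c(16, 16, 16))
  vol <- volume3d(vals, spacing = c(2, 2, 2))
  zero <- dvf_volume(array(0, c(16, 16, 16, 3)), spacing = c(2, 2, 2))
  expect_identical(warp_volume(vol, zero)$values, vol$values)
  # constant +2 voxel shift along x (pull-back: content moves -x)
  shift <- zero
  shift$displacement[, , , 1] <- 4
  w <- warp_volume(vol, shift)
  expect_equal(w$values[1:14, , ], vol$values[3:16, , ], tolerance = 1e-12)
  expect_true(all(w$values[15:16, , ] == 0))
  # linear ramp under constant displacement: analytic shifted ramp
  ramp <- volume3d(array(rep(seq(0, 30, by = 2), each = 1), c(16, 16, 16)),
                   spacing = c(2, 2, 2))
  const <- zero
  const$displacement[, , , 1] <- 1.3
  wr <- warp_volume(ramp, const)
  interior <- 2:15
  expect_equal(wr$values[interior, , ],
               ramp$values[interior, , ] + 1.3, tolerance = 1e-6)
  expect_error(warp_volume(vol, small_4dct()$dvfs[[2]]), "grid")
})

test_that("phantom DVFs warp the reference onto each phase volume", {
  spec <- default_spec()
  ref <- default_4dct()$volumes[[1]]
  d <- dim(ref$values); int <- 4:(d[1] - 3)
  a <- 0.8
  w <- warp_volume(ref, ground_truth_dvf(spec, a))
  truth <- make_phantom(spec, a)
  expect_gte(ncc(w$values[int, int, int], truth$values[int, int, int]), 0.99)
})

test_that("motion models serialize losslessly", {
  model <- small_pca()
  f <- tempfile(fileext = ".rds")
  save_motion_model(model, f)
  m2 <- load_motion_model(f)
  expect_equal(m2$basis, model$basis)
  expect_equal(m2$mean_dvf, model$mean_dvf)
  expect_s3_class(m2, "pca_motion_model")
  unlink(f)
})
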