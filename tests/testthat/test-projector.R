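test_that("a uniform cube projects to its analytic path integral", {
  # mu = 0.02 /mm over a 100 mm cube: central perpendicular ray -> 2.0
  vol <- volume3d(array(0.02, c(25, 25, 25)), rep(4, 3))
  geom <- cone_beam_geometry(sad = 1000, sdd = 1500,
                             detector_size = c(33L, 33L), pixel_pitch = 8,
                             isocenter = c(48, 48, 48))
  drr <- forward_project(vol, geom)
  expect_equal(drr$values[17, 17], 2, tolerance = 1e-6)
})

test_that("an empty volume projects to exactly zero", {
  vol <- volume3d(array(0, c(8, 8, 8)), rep(4, 3))
  geom <- cone_beam_geometry(detector_size = c(8L, 8L), pixel_pitch = 8,
                             isocenter = c(14, 14, 14))
  expect_true(all(forward_project(vol, geom)$values == 0))
})

test_that("the projector is linear in the volume", {
  set.seed(20)
  a <- array(runif(16^3), c(16, 16, 16))
  b <- array(runif(16^3), c(16, 16, 16))
  geom <- cone_beam_geometry(detector_size = c(16L, 16L), pixel_pitch = 8,
                             isocenter = c(30, 30, 30))
  pa <- forward_project(volume3d(a, rep(4, 3)), geom)$values
  pb <- forward_project(volume3d(b, rep(4, 3)), geom)$values
  pc <- forward_project(volume3d(2 * a + 3 * b, rep(4, 3)), geom)$values
  expect_equal(pc, 2 * pa + 3 * pb, tolerance = 1e-6)
})

test_that("Siddon agrees with a dense ray-marching oracle within 0.5%", {
  set.seed(21)
  vol <- volume3d(array(runif(16^3), c(16, 16, 16)), rep(4, 3))
  geom <- cone_beam_geometry(detector_size = c(16L, 16L), pixel_pitch = 8,
                             isocenter = c(30, 30, 30))
  ds <- forward_project(vol, geom)$values
  dm <- raymarch_project(vol, geom)
  sel <- dm > 0.5 * max(dm)
  expect_lt(max(abs(ds[sel] - dm[sel]) / dm[sel]), 0.005)
})

test_that("shifting the volume shifts the DRR by the magnified amount", {
  # slab at the isocenter plane, magnification SDD/SAD = 2: a one-voxel
  # (4 mm) lateral shift moves the projection by one 8 mm detector pixel
  vals <- array(0, c(24, 24, 24))
  set.seed(22)
  vals[5:20, 12, 5:20] <- runif(16 * 16) + 0.5
  geom <- cone_beam_geometry(sad = 500, sdd = 1000,
                             detector_size = c(24L, 24L), pixel_pitch = 8,
                             isocenter = c(46, 46, 46))
  # the empty corners of the bounding box fall outside the small panel, so
  # silence the footprint warning; all non-zero voxels project onto it
  p0 <- suppressWarnings(forward_project(volume3d(vals, rep(4, 3)), geom)$values)
  shifted <- array(0, c(24, 24, 24))
  shifted[6:21, 12, 5:20] <- vals[5:20, 12, 5:20]
  p1 <- suppressWarnings(forward_project(volume3d(shifted, rep(4, 3)),
                                         geom)$values)
  inner <- 4:21
  expect_lt(max(abs(p1[inner + 1, inner] - p0[inner, inner])),
            0.02 * max(p0))
})

test_that("projection geometry is validated and footprint warnings fire", {
  expect_error(cone_beam_geometry(sad = 1500, sdd = 1000), "SDD > SAD")
  expect_error(cone_beam_geometry(pixel_pitch = 0), "pitch")
  vol <- volume3d(array(0.01, c(16, 16, 16)), rep(8, 3))
  tiny_panel <- cone_beam_geometry(detector_size = c(4L, 4L), pixel_pitch = 4,
                                   isocenter = c(60, 60, 60))
  expect_warning(forward_project(vol, tiny_panel), "footprint")
})

test_that("noise injection follows the Poisson-plus-Gaussian law", {
  I0 <- 1e5; s2 <- 10
  pnv <- 1.5
  drr <- structure(list(values = matrix(pnv, 320, 320), geometry = NULL,
                        noisy = FALSE), class = "drr_image")
  noisy <- add_noise(drr, noise_model(I0, s2, seed = 31))
  I <- I0 * exp(-noisy$values)
  lambda <- I0 * exp(-pnv)
  n <- length(I)
  expect_lt(abs(mean(I) - lambda), 3 * sqrt((lambda + s2) / n))
  expect_lt(abs(stats::var(as.numeric(I)) / (lambda + s2) - 1), 0.05)
})

test_that("noise vanishes in the high-intensity limit and reproduces", {
  set.seed(30)
  pn <- matrix(runif(1e4, 2, 5), 100, 100)
  drr <- structure(list(values = pn, geometry = NULL, noisy = FALSE),
                   class = "drr_image")
  quiet <- add_noise(drr, noise_model(I0 = 1e10, sigma_e2 = 0, seed = 32))
  expect_lt(max(abs(quiet$values - pn)), 1e-3)
  a <- add_noise(drr, noise_model(seed = 33))
  b <- add_noise(drr, noise_model(seed = 33))
  expect_identical(a$values, b$values)
  expect_true(a$noisy)
  # extreme attenuation triggers the one-photon clamp path
  dark <- structure(list(values = matrix(30, 4, 4), geometry = NULL,
                         noisy = FALSE), class = "drr_image")
  expect_message(add_noise(dark, noise_model(seed = 34)), "clamped")
})

test_that("intensity correction matches moments and its printed variant", {
  img <- matrix(c(0, 1, 2, 3), 2, 2)
  ds <- intensity_stats_of(img)
  # fixed point when both stats agree
  same <- intensity_correct(img, ds, ds)
  expect_equal(same, img, tolerance = 1e-6)
  # moment matching reaches the target moments exactly
  ps <- intensity_stats(10, 2 * ds$std)
  out <- intensity_correct(img, ds, ps)
  expect_equal(mean(out), 10, tolerance = 1e-6)
  expect_equal(stats::sd(as.numeric(out)), 2 * ds$std, tolerance = 1e-6)
  expect_equal(out, (img - 1.5) / ds$std * (2 * ds$std) + 10,
               tolerance = 1e-12)
  # literal published formula, per-pixel reading
  lit <- intensity_correct(img, ds, ps, mode = "as-printed")
  expect_equal(lit, (img - 10) * ds$std / (2 * ds$std) + img,
               tolerance = 1e-12)
  expect_error(intensity_correct(img, ds, intensity_stats(0, 0)), "positive")
  expect_warning(intensity_correct(img, intensity_stats(1.5, 0), ps),
                 "constant")
})

test_that("DRRs round-trip through 32-bit TIFF with geometry sidecars", {
  vol <- volume3d(array(0.01, c(16, 16, 16)), rep(4, 3))
  geom <- cone_beam_geometry(detector_size = c(16L, 16L), pixel_pitch = 8,
                             isocenter = c(30, 30, 30))
  drr <- forward_project(vol, geom)
  f <- tempfile(fileext = ".tif")
  write_drr_tiff(drr, f)
  back <- read_drr_tiff(f)
  expect_equal(back$values, drr$values, tolerance = 1e-6, ignore_attr = TRUE)
  expect_equal(back$geometry$sad, geom$sad)
  expect_equal(back$geometry$detector_size, geom$detector_size)
  unlink(c(f, paste0(f, ".json")))
})
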