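# Shared fixtures, built once per test run and cached.

.fixtures <- new.env(parent = emptyenv())

memo <- function(name, expr) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- force(expr)
  .fixtures[[name]]
}

# 32^3 phantom keeps the 256 mm field of view of the default spec.
small_spec <- function() memo("small_spec",
  phantom_spec(grid_dims = c(32L, 32L, 32L), spacing = rep(8, 3)))

# Default-resolution phantom (64^3 at 4 mm), for the warp-closure bounds
# whose interpolation error depends on voxel size.
default_spec <- function() memo("default_spec", phantom_spec())

default_4dct <- function() memo("default_4dct",
  generate_4dct(default_spec(), breathing_trace(10)))

small_4dct <- function() memo("small_4dct",
  generate_4dct(small_spec(), breathing_trace(10)))

small_pca <- function() memo("small_pca", fit_pca(small_4dct()$dvfs[-1], k = 3))

small_phase_coeffs <- function() memo("small_phase_coeffs", {
  t(vapply(small_4dct()$dvfs, function(d) project_dvf(small_pca(), d),
           numeric(3)))
})

small_geom <- function()
  cone_beam_geometry(detector_size = c(32L, 32L), pixel_pitch = 12)

# A tiny trained model over the real pipeline (32^3 phantom, 32^2 DRRs),
# shared by the reconstruction tests.
small_trained <- function() memo("small_trained", {
  cfg <- experiment_config(
    grid_dims = c(32L, 32L, 32L), spacing = rep(8, 3),
    n_sequences = 60L,
    geometry = small_geom(),
    net = network_config(hidden_channels = 4L, input_dim = c(32L, 32L),
                         pool_channels = 2L, fc_dim = 64L),
    train = training_config(epochs = 6L),
    seed = 42L)
  list(config = cfg, report = run_experiment(cfg))
})

# Small learnable synthetic sequence-regression task: a Gaussian blob whose
# horizontal drift encodes the first target and vertical position the
# second. Exercises the spatiotemporal path without the projection stack.
toy_dataset <- function(n = 80L, h = 16L, T_ = 3L, seed = 3L, k = 2L) {
  set.seed(seed)
  X <- array(0, c(h, h, T_, n)); Y <- matrix(0, n, k)
  xs <- outer(seq_len(h), rep(1, h)); ys <- t(xs)
  for (i in seq_len(n)) {
    cx <- stats::runif(1, 5, h - 4); cy <- stats::runif(1, 5, h - 4)
    for (t in seq_len(T_))
      X[, , t, i] <- exp(-((xs - cx - 0.5 * t)^2 + (ys - cy)^2) / 4) +
        0.05 * stats::rnorm(h * h)
    Y[i, ] <- c(cx, cy)[seq_len(k)]
  }
  list(sequences = X, labels = Y)
}
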