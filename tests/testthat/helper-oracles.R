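# Independent oracles, implemented without reusing the package's production
# code paths.

# Dense ray-marching projector: nearest-voxel sampling at a fine step along
# each source->pixel ray. Brute force; checks the Siddon traversal.
raymarch_project <- function(vol, geom, step_vox = 0.02) {
  fr <- rt4dcbct:::geometry_frame(geom, vol)
  pix <- rt4dcbct:::detector_pixel_positions(geom, fr)
  h <- min(vol$spacing) * step_vox
  dm <- dim(vol$values)
  out <- numeric(length(pix$x))
  for (p in seq_along(pix$x)) {
    d <- c(pix$x[p], pix$y[p], pix$z[p]) - fr$source
    len <- sqrt(sum(d^2)); dir <- d / len
    ts <- seq(h / 2, len, by = h)
    pts <- cbind(fr$source[1] + ts * dir[1],
                 fr$source[2] + ts * dir[2],
                 fr$source[3] + ts * dir[3])
    ci <- round(sweep(sweep(pts, 2, vol$origin, "-"), 2, vol$spacing, "/")) + 1
    ok <- ci[, 1] >= 1 & ci[, 1] <= dm[1] &
          ci[, 2] >= 1 & ci[, 2] <= dm[2] &
          ci[, 3] >= 1 & ci[, 3] <= dm[3]
    idx <- ci[ok, 1] + (ci[ok, 2] - 1) * dm[1] + (ci[ok, 3] - 1) * dm[1] * dm[2]
    out[p] <- sum(vol$values[idx]) * h
  }
  matrix(out, geom$detector_size[1], geom$detector_size[2])
}

# Scalar (non-convolutional) LSTM stepped by hand; the ConvLSTM cell on a
# 1x1 same-padded grid must reduce to it with the centre kernel taps.
scalar_lstm_step <- function(x, h, c_, wx, wh, b) {
  sig <- function(z) 1 / (1 + exp(-z))
  i_ <- sig(wx[1] * x + wh[1] * h + b[1])
  f_ <- sig(wx[2] * x + wh[2] * h + b[2])
  o_ <- sig(wx[3] * x + wh[3] * h + b[3])
  g_ <- tanh(wx[4] * x + wh[4] * h + b[4])
  c_ <- f_ * c_ + i_ * g_
  list(h = o_ * tanh(c_), c = c_)
}

# Direct nested-loop 3x3 convolution (stride 1) of an (h, w, cin) array with
# weights in the package layout ((cin-1)*9 + kr + 3*kc + 1, cout).
naive_conv3 <- function(X, W, bias = NULL, pad = 0L) {
  h <- dim(X)[1]; w <- dim(X)[2]; cin <- dim(X)[3]
  cout <- ncol(W)
  hp <- h + 2L * pad; wp <- w + 2L * pad
  Xp <- array(0, c(hp, wp, cin))
  Xp[(pad + 1):(pad + h), (pad + 1):(pad + w), ] <- X
  ho <- hp - 2L; wo <- wp - 2L
  out <- array(0, c(ho, wo, cout))
  for (co in seq_len(cout)) {
    for (ci in seq_len(cin)) for (kc in 0:2) for (kr in 0:2) {
      wgt <- W[(ci - 1L) * 9L + kr + 3L * kc + 1L, co]
      if (wgt != 0)
        out[, , co] <- out[, , co] +
          wgt * Xp[(1 + kr):(ho + kr), (1 + kc):(wo + kc), ci]
    }
    if (!is.null(bias)) out[, , co] <- out[, , co] + bias[co]
  }
  out
}

# SSIM via scikit-image (Wang et al. preset), used as the independent
# cross-implementation reference.
skimage_ssim <- function(pairs, data_range) {
  td <- tempfile("ssimref"); dir.create(td)
  on.exit(unlink(td, recursive = TRUE))
  for (i in seq_along(pairs)) {
    utils::write.table(pairs[[i]]$a, file.path(td, sprintf("a%d.txt", i)),
                       row.names = FALSE, col.names = FALSE)
    utils::write.table(pairs[[i]]$b, file.path(td, sprintf("b%d.txt", i)),
                       row.names = FALSE, col.names = FALSE)
  }
  script <- file.path(td, "ssim.py")
  writeLines(c(
    "import sys, numpy as np",
    "from skimage.metrics import structural_similarity",
    "d = sys.argv[1]; n = int(sys.argv[2]); dr = float(sys.argv[3])",
    "for i in range(1, n + 1):",
    "    a = np.loadtxt(f'{d}/a{i}.txt'); b = np.loadtxt(f'{d}/b{i}.txt')",
    "    s = structural_similarity(a, b, gaussian_weights=True, sigma=1.5,",
    "                              use_sample_covariance=False, data_range=dr)",
    "    print(f'{float(s):.15g}')"), script)
  out <- system2("python", c(script, td, length(pairs), data_range),
                 stdout = TRUE)
  as.numeric(out)
}
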