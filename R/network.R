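#' ConvLSTM network configuration
#'
#' Architecture hyper-parameters of the coefficient-regression network:
#' stacked ConvLSTM cells (3x3 kernels, stride 1; "valid" padding on every
#' input path, "same" padding on the recurrent path) followed by a
#' regression head made of one convolutional-pooling stage (3x3 convolution,
#' stride 2, ReLU - a 2x down-sampling) and two fully connected layers of
#' dimensions `fc_dim` and `k`.
#'
#' Defaults follow the ablation optimum: 40 hidden channels, two cell
#' layers, input sequences of four consecutive frames, fully connected
#' width 1024, three output coefficients.
#'
#' @param hidden_channels hidden/cell feature channels per ConvLSTM layer.
#' @param cell_layers number of stacked ConvLSTM layers.
#' @param sequence_length number of consecutive DRR frames `T` per input.
#' @param input_dim `(h, w)` pixel size of one input frame.
#' @param k number of regressed PCA coefficients.
#' @param pool_channels channels of the pooling convolution (default
#'   `max(2, hidden_channels / 4)`).
#' @param fc_dim width of the first fully connected layer.
#' @param pooling `"convolutional"` (default) applies the stride-2
#'   convolutional pooling stage; `"none"` feeds the flattened hidden map
#'   directly to the fully connected layers (kept for ablation of the
#'   pooling choice).
#' @return object of class `network_config`.
#' @export
network_config <- function(hidden_channels = 40L, cell_layers = 2L,
                           sequence_length = 4L, input_dim = c(64L, 64L),
                           k = 3L, pool_channels = NULL, fc_dim = 1024L,
                           pooling = c("convolutional", "none")) {
  pooling <- match.arg(pooling)
  if (sequence_length < 1L) stop("sequence_length must be >= 1")
  if (cell_layers < 1L) stop("cell_layers must be >= 1")
  if (is.null(pool_channels))
    pool_channels <- max(2L, as.integer(hidden_channels) %/% 4L)
  cfg <- list(hidden_channels = as.integer(hidden_channels),
              cell_layers = as.integer(cell_layers),
              sequence_length = as.integer(sequence_length),
              input_dim = as.integer(input_dim),
              k = as.integer(k),
              pool_channels = as.integer(pool_channels),
              fc_dim = as.integer(fc_dim),
              pooling = pooling)
  if (cfg$input_dim[1] - 2L * cfg$cell_layers < 3L)
    stop("input too small for the requested number of cell layers")
  structure(cfg, class = "network_config")
}

#' Training configuration
#'
#' ADAM with a step-decayed learning rate (initial 0.001, halved every
#' `lr_decay_every` epochs), batch size 8, coefficient loss weights
#' `wcoeff = c(2/6, 1/6, 1/6)` applied to per-component standardized
#' targets. The published regime trains 200 epochs; desk-scale experiments
#' use far fewer (see the package vignette).
#'
#' @param epochs training epochs.
#' @param batch_size mini-batch size (>= 1).
#' @param initial_lr initial ADAM learning rate.
#' @param lr_decay_factor,lr_decay_every step decay of the learning rate.
#' @param wcoeff positive loss weights, length `k`.
#' @param val_fraction fraction of samples held out for validation.
#' @param clip_norm global gradient-norm clip (Inf disables).
#' @param seed RNG seed for initialization, shuffling and splitting.
#' @return object of class `training_config`.
#' @export
training_config <- function(epochs = 200L, batch_size = 8L,
                            initial_lr = 1e-3, lr_decay_factor = 0.5,
                            lr_decay_every = 50L,
                            wcoeff = c(2, 1, 1) / 6,
                            val_fraction = 0.1, clip_norm = 5,
                            seed = 1L) {
  if (batch_size < 1L) stop("batch_size must be >= 1")
  if (any(wcoeff <= 0)) stop("wcoeff entries must be positive")
  structure(list(epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 initial_lr = initial_lr,
                 lr_decay_factor = lr_decay_factor,
                 lr_decay_every = as.integer(lr_decay_every),
                 wcoeff = wcoeff, val_fraction = val_fraction,
                 clip_norm = clip_norm, seed = as.integer(seed)),
            class = "training_config")
}

#' Weighted coefficient regression loss
#'
#' `(1/N) sum_i || wcoeff o (y_i - yhat_i) ||^2` over a batch: a weighted
#' mean squared error whose weights bias training accuracy towards the
#' first (dominant-motion) PCA coefficient.
#'
#' @param y,y_hat `N x k` matrices (or length-k vectors) of target and
#'   predicted coefficients.
#' @param wcoeff positive weight vector of length `k`.
#' @return scalar loss.
#' @export
weighted_loss <- function(y, y_hat, wcoeff = c(2, 1, 1) / 6) {
  y <- rbind(y); y_hat <- rbind(y_hat)
  if (!all(dim(y) == dim(y_hat))) stop("shape mismatch between y and y_hat")
  if (length(wcoeff) != ncol(y)) stop("wcoeff length must equal k")
  r <- sweep(y - y_hat, 2, wcoeff, "*")
  sum(r^2) / nrow(y)
}

flatten_params <- function(p) {
  v <- list()
  for (l in seq_along(p$layers)) v <- c(v, p$layers[[l]][c("Wx", "Wh", "b")])
  c(v, p[c("Wp", "bp", "W1", "b1", "W2", "b2")])
}

map_params <- function(p, g, fun) {
  for (l in seq_along(p$layers))
    for (nm in c("Wx", "Wh", "b"))
      p$layers[[l]][[nm]] <- fun(p$layers[[l]][[nm]], g$layers[[l]][[nm]])
  for (nm in c("Wp", "bp", "W1", "b1", "W2", "b2"))
    p[[nm]] <- fun(p[[nm]], g[[nm]])
  p
}

grad_global_norm <- function(g) {
  sqrt(sum(vapply(flatten_params(g), function(x) sum(x^2), numeric(1))))
}

adam_state_like <- function(p) map_params(p, p, function(a, b) a * 0)

#' Train the ConvLSTM coefficient regressor
#'
#' Full-batch shuffled mini-batch training with ADAM and the weighted loss
#' of [weighted_loss()]. Targets are standardized per component (zero mean,
#' unit variance over the training split) before the loss; the scaler is
#' stored with the model so [predict_coefficients()] returns coefficients
#' in original units. Runs are reproducible for a fixed seed on one
#' machine.
#'
#' @param dataset list with `sequences`, an array `(h, w, T, n)` of
#'   normalized DRR frames, and `labels`, an `n x k` coefficient matrix in
#'   raw units.
#' @param net_config a [network_config()].
#' @param train_config a [training_config()].
#' @param verbose print per-epoch losses.
#' @return object of class `convlstm_model`: `params`, `net_config`,
#'   `train_config`, `scaler` (`center`, `scale` per component) and
#'   `history` (per-epoch data frame with training and validation loss).
#' @export
train_network <- function(dataset, net_config, train_config,
                          verbose = FALSE) {
  X <- dataset$sequences
  Y <- as.matrix(dataset$labels)
  if (is.null(dim(X)) || length(dim(X)) != 4L) stop("sequences must be (h, w, T, n)")
  n <- dim(X)[4]
  if (n == 0L || nrow(Y) != n) stop("empty dataset or label mismatch")
  if (dim(X)[3] != net_config$sequence_length)
    stop("sequence length does not match the network configuration")
  k <- net_config$k
  if (ncol(Y) != k) stop("labels must have k columns")
  wc <- train_config$wcoeff
  if (length(wc) != k) stop("wcoeff length must equal k")

  set.seed(train_config$seed)
  params <- init_network(net_config, seed = train_config$seed)
  center <- colMeans(Y)
  scale_ <- apply(Y, 2, stats::sd)
  scale_[scale_ == 0] <- 1
  Ys <- sweep(sweep(Y, 2, center, "-"), 2, scale_, "/")

  n_val <- max(0L, round(train_config$val_fraction * n))
  perm <- sample.int(n)
  val_idx <- if (n_val > 0L) perm[seq_len(n_val)] else integer(0)
  tr_idx <- setdiff(perm, val_idx)
  m <- adam_state_like(params)
  v <- adam_state_like(params)
  beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
  step <- 0L
  history <- data.frame(epoch = integer(0), lr = numeric(0),
                        train_loss = numeric(0), val_loss = numeric(0))

  eval_loss <- function(idx) {
    if (length(idx) == 0L) return(NA_real_)
    tot <- 0
    bs <- max(train_config$batch_size, 8L)
    for (s in split(idx, ceiling(seq_along(idx) / bs))) {
      fw <- forward_convlstm(params, X[, , , s, drop = FALSE], net_config)
      tot <- tot + weighted_loss(Ys[s, , drop = FALSE], fw$out, wc) * length(s)
    }
    tot / length(idx)
  }

  for (ep in seq_len(train_config$epochs)) {
    lr <- train_config$initial_lr *
      train_config$lr_decay_factor^((ep - 1L) %/% train_config$lr_decay_every)
    ord <- sample(tr_idx)
    ep_loss <- 0
    batches <- split(ord, ceiling(seq_along(ord) / train_config$batch_size))
    for (bt in batches) {
      fw <- forward_convlstm(params, X[, , , bt, drop = FALSE], net_config,
                             keep_cache = TRUE)
      resid <- fw$out - Ys[bt, , drop = FALSE]
      loss <- sum(sweep(resid, 2, wc, "*")^2) / length(bt)
      ep_loss <- ep_loss + loss * length(bt)
      dOut <- sweep(resid, 2, 2 * wc^2 / length(bt), "*")
      grads <- backward_convlstm(params, net_config, fw$cache, dOut)
      gn <- grad_global_norm(grads)
      if (is.finite(train_config$clip_norm) && gn > train_config$clip_norm)
        grads <- map_params(grads, grads,
                            function(a, b) a * (train_config$clip_norm / gn))
      step <- step + 1L
      bc1 <- 1 - beta1^step; bc2 <- 1 - beta2^step
      m <- map_params(m, grads, function(a, g) beta1 * a + (1 - beta1) * g)
      v <- map_params(v, grads, function(a, g) beta2 * a + (1 - beta2) * g^2)
      upd <- map_params(m, v, function(a, b)
        lr * (a / bc1) / (sqrt(b / bc2) + eps))
      params <- map_params(params, upd, function(p, u) p - u)
    }
    ep_loss <- ep_loss / length(ord)
    vl <- eval_loss(val_idx)
    history <- rbind(history, data.frame(epoch = ep, lr = lr,
                                         train_loss = ep_loss, val_loss = vl))
    if (verbose)
      message(sprintf("epoch %3d  lr %.2e  train %.5f  val %s",
                      ep, lr, ep_loss,
                      ifelse(is.na(vl), "-", sprintf("%.5f", vl))))
  }
  structure(list(params = params, net_config = net_config,
                 train_config = train_config,
                 scaler = list(center = center, scale = scale_),
                 history = history),
            class = "convlstm_model")
}

#' @export
print.convlstm_model <- function(x, ...) {
  np <- sum(vapply(flatten_params(x$params), length, numeric(1)))
  cat(sprintf(
    "<convlstm_model> %d hidden x %d layers, T = %d, %.2fM parameters, %d epochs (final train loss %.4g)\n",
    x$net_config$hidden_channels, x$net_config$cell_layers,
    x$net_config$sequence_length, np / 1e6, nrow(x$history),
    utils::tail(x$history$train_loss, 1)))
  invisible(x)
}

#' Predict PCA coefficients from DRR sequences
#'
#' Forward pass of a trained model followed by de-standardization, returning
#' coefficients in the original (raw) units.
#'
#' @param model a [train_network()] result.
#' @param sequences array `(h, w, T)` for one sequence or `(h, w, T, n)`.
#' @return `n x k` coefficient matrix.
#' @export
predict_coefficients <- function(model, sequences) {
  if (is.null(model$scaler)) stop("model is missing its target scaler")
  d <- dim(sequences)
  if (length(d) == 3L) dim(sequences) <- c(d, 1L)
  if (dim(sequences)[3] != model$net_config$sequence_length)
    stop("sequence length mismatch")
  out <- forward_convlstm(model$params, sequences, model$net_config)$out
  sweep(sweep(out, 2, model$scaler$scale, "*"), 2, model$scaler$center, "+")
}

#' Normalize a DRR frame for network input
#'
#' Per-image z-score normalization applied after noise injection and
#' intensity correction, the standard conditioning for projection-domain
#' network inputs.
#'
#' @param drr a [drr_image()] or numeric matrix.
#' @return numeric matrix with zero mean and unit variance.
#' @export
normalize_drr <- function(drr) {
  v <- if (inherits(drr, "drr_image")) drr$values else drr
  s <- stats::sd(as.numeric(v))
  if (s == 0) return(v * 0)
  (v - mean(v)) / s
}

simulate_drr_frame <- function(pca_model, q, reference, geom, noise = NULL) {
  vol <- warp_volume(reference, synthesize_dvf(pca_model, q))
  drr <- suppressWarnings(forward_project(vol, geom))
  if (!is.null(noise)) drr <- add_noise(drr, noise)
  normalize_drr(drr)
}

#' Simulate temporally ordered DRR training sequences
#'
#' The published pipeline trains on ~900 randomly sampled coefficient sets
#' but feeds the network sequences of consecutive frames; this generator
#' gives the random samples temporal structure by laying them out along
#' simulated breathing traces in coefficient space. Each trace follows the
#' periodic coefficient trajectory through the planning phases
#' ([coefficient_trajectory()]), scaled by a per-trace factor drawn
#' uniformly from the +/- `expansion` range and offset by a small
#' per-component jitter; consecutive frames are one phase bin apart, and
#' frames `t-T+1 ... t` form the sequence labelled with the coefficients of
#' frame `t`. Every frame is rendered by deforming the reference volume
#' with the synthesized DVF, projecting it at the fixed gantry angle,
#' adding quantum noise and z-scoring.
#'
#' @param pca_model a [fit_pca()] model.
#' @param phase_coeffs `n_phases x k` matrix of per-phase coefficients.
#' @param reference reference-phase [volume3d()].
#' @param geom a [cone_beam_geometry()].
#' @param noise a [noise_model()] or `NULL` for noise-free frames.
#' @param n_sequences number of labelled sequences to generate.
#' @param sequence_length frames per sequence `T`.
#' @param expansion per-trace amplitude scale range (default 0.15: scales
#'   drawn from `[0.85, 1.15]`).
#' @param jitter per-component additive jitter, as a fraction of the
#'   per-component phase range.
#' @param windows_per_trace labelled windows cut from each simulated trace.
#' @param seed RNG seed.
#' @return list with `sequences` array `(h, w, T, n)`, `labels`
#'   (`n x k`, raw units), and `frame_log` (data.frame of trace, phase
#'   position, scale per labelled frame).
#' @export
simulate_training_sequences <- function(pca_model, phase_coeffs, reference,
                                        geom, noise = NULL,
                                        n_sequences = 300L,
                                        sequence_length = 4L,
                                        expansion = 0.15, jitter = 0.02,
                                        windows_per_trace = 10L,
                                        seed = 1L) {
  set.seed(seed)
  traj <- coefficient_trajectory(phase_coeffs)
  n_phases <- nrow(phase_coeffs)
  k <- ncol(phase_coeffs)
  rng <- apply(phase_coeffs, 2, function(x) diff(range(x)))
  T_ <- as.integer(sequence_length)
  wpt <- as.integer(windows_per_trace)
  n_traces <- ceiling(n_sequences / wpt)
  nu <- geom$detector_size[1]; nv <- geom$detector_size[2]
  seqs <- array(0, c(nu, nv, T_, n_sequences))
  labels <- matrix(0, n_sequences, k)
  log_rows <- vector("list", n_sequences)
  s_i <- 0L
  for (tr in seq_len(n_traces)) {
    scale_tr <- stats::runif(1, 1 - expansion, 1 + expansion)
    jit <- stats::runif(k, -jitter, jitter) * rng
    phi0 <- stats::runif(1, 0, n_phases)
    L <- T_ + wpt - 1L
    phis <- phi0 + seq_len(L) - 1
    qs <- sweep(scale_tr * traj(phis), 2, jit, "+")
    frames <- array(0, c(nu, nv, L))
    for (f in seq_len(L))
      frames[, , f] <- simulate_drr_frame(pca_model, qs[f, ], reference,
                                          geom, noise)
    for (wnd in seq_len(wpt)) {
      if (s_i >= n_sequences) break
      s_i <- s_i + 1L
      seqs[, , , s_i] <- frames[, , wnd:(wnd + T_ - 1L)]
      labels[s_i, ] <- qs[wnd + T_ - 1L, ]
      log_rows[[s_i]] <- data.frame(trace = tr, phase = phis[wnd + T_ - 1L],
                                    scale = scale_tr)
    }
    if (s_i >= n_sequences) break
  }
  list(sequences = seqs, labels = labels,
       frame_log = do.call(rbind, log_rows))
}

#' Simulate an online projection stream covering one breathing cycle
#'
#' Renders `n_phases + T - 1` consecutive frames along the unscaled
#' periodic phase trajectory, starting `T - 1` frames before phase 0, so
#' that the sliding windows of [reconstruct_cycle()] label each phase of
#' the cycle exactly once.
#'
#' @inheritParams simulate_training_sequences
#' @param sequence_length window length `T`.
#' @return list with `frames` array `(h, w, n_phases + T - 1)`, `phases`
#'   (0-based phase labelled by each window), and `labels` (`n_phases x k`
#'   true coefficients).
#' @export
simulate_phase_stream <- function(pca_model, phase_coeffs, reference, geom,
                                  noise = NULL, sequence_length = 4L,
                                  seed = 1L) {
  set.seed(seed)
  traj <- coefficient_trajectory(phase_coeffs)
  n_phases <- nrow(phase_coeffs)
  T_ <- as.integer(sequence_length)
  phis <- seq(-(T_ - 1L), n_phases - 1L)
  qs <- traj(phis)
  nu <- geom$detector_size[1]; nv <- geom$detector_size[2]
  frames <- array(0, c(nu, nv, length(phis)))
  for (f in seq_along(phis))
    frames[, , f] <- simulate_drr_frame(pca_model, qs[f, ], reference, geom,
                                        noise)
  list(frames = frames, phases = 0:(n_phases - 1L),
       labels = qs[T_:length(phis), , drop = FALSE])
}
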