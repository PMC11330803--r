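test_that("weighted loss matches hand calculations and homogeneity", {
  y <- matrix(c(1, 2, 3), 1)
  expect_equal(weighted_loss(y, y), 0)
  # residual (3,3,3) with weights (2/6,1/6,1/6): ||(1, .5, .5)||^2 = 1.5
  expect_equal(weighted_loss(y + 3, y), 1.5)
  set.seed(40)
  a <- matrix(rnorm(12), 4); b <- matrix(rnorm(12), 4)
  expect_equal(weighted_loss(a, 2 * b - a), 4 * weighted_loss(a, b))
  expect_error(weighted_loss(a, b, wcoeff = c(1, 1)), "length")
  expect_error(weighted_loss(a, b[1:2, ]), "shape")
})

test_that("zero kernels and zero state keep the cell silent", {
  prm <- list(Wx = matrix(0, 9, 4), Wh = matrix(0, 9, 4), b = rep(0, 4))
  st <- NULL
  X <- array(rnorm(25), c(5, 5, 1))
  for (t in 1:4) {
    st <- convlstm_cell_step(X, st[c("H", "C")], prm, pad_x = "same")
    expect_true(all(st$C == 0))
    expect_true(all(st$H == 0))
  }
})

test_that("the cell at 1x1 spatial size equals a scalar LSTM", {
  set.seed(41)
  prm <- list(Wx = matrix(rnorm(9 * 4), 9, 4),
              Wh = matrix(rnorm(9 * 4), 9, 4), b = rnorm(4))
  # centre taps (kr = kc = 1 -> row 5) are the only ones that see the input
  wx <- prm$Wx[5, ]; wh <- prm$Wh[5, ]
  xseq <- rnorm(6)
  h <- 0; c_ <- 0; st <- NULL
  for (t in seq_along(xseq)) {
    st <- convlstm_cell_step(array(xseq[t], c(1, 1, 1)), st[c("H", "C")],
                             prm, pad_x = "same")
    o <- scalar_lstm_step(xseq[t], h, c_, wx, wh, prm$b)
    h <- o$h; c_ <- o$c
    expect_equal(st$H[1, 1, 1], h, tolerance = 1e-10)
    expect_equal(st$C[1, 1, 1], c_, tolerance = 1e-10)
  }
})

test_that("gates stay in (0, 1) and states bounded over random steps", {
  set.seed(42)
  prm <- list(Wx = matrix(rnorm(9 * 2 * 4 * 3, sd = 0.5), 9 * 2, 4 * 3),
              Wh = matrix(rnorm(9 * 3 * 4 * 3, sd = 0.5), 9 * 3, 4 * 3),
              b = rnorm(12))
  st <- NULL
  for (t in 1:50) {
    X <- array(rnorm(6 * 6 * 2, sd = 2), c(6, 6, 2))
    st <- convlstm_cell_step(X, st[c("H", "C")], prm, pad_x = "same")
    for (g in c("i", "f", "o"))
      expect_true(all(st[[g]] > 0 & st[[g]] < 1))
    expect_true(all(abs(st$H) < 1))
    expect_true(all(is.finite(st$C)))
  }
  expect_error(convlstm_cell_step(array(0, c(4, 4, 3)), NULL,
                                  list(Wx = matrix(0, 9, 4),
                                       Wh = matrix(0, 9, 4), b = rep(0, 4))),
               "channel mismatch")
})

test_that("the batched forward pass agrees with a naive convolution network", {
  cfg <- network_config(hidden_channels = 2L, cell_layers = 2L,
                        sequence_length = 3L, input_dim = c(9L, 9L),
                        k = 2L, pool_channels = 2L, fc_dim = 5L)
  params <- init_network(cfg, seed = 50)
  set.seed(51)
  X <- array(rnorm(9 * 9 * 3 * 2), c(9, 9, 3, 2))
  out <- rt4dcbct:::forward_convlstm(params, X, cfg)$out
  # independent re-evaluation: naive convolutions + explicit gate algebra
  sig <- function(z) 1 / (1 + exp(-z))
  for (b in 1:2) {
    maps <- lapply(1:3, function(t) array(X[, , t, b], c(9, 9, 1)))
    for (l in 1:2) {
      p <- params$layers[[l]]
      H <- NULL; C <- NULL
      hw <- dim(maps[[1]])[1] - 2L
      H <- array(0, c(hw, hw, 2)); C <- H
      outs <- list()
      for (t in 1:3) {
        zx <- naive_conv3(maps[[t]], p$Wx, pad = 0L)
        zh <- naive_conv3(H, p$Wh, pad = 1L)
        z <- zx + zh
        gi <- sig(z[, , 1:2] + rep(p$b[1:2], each = hw * hw) * 0 +
                    aperm(array(p$b[1:2], c(2, hw, hw)), c(2, 3, 1)))
        gf <- sig(z[, , 3:4] + aperm(array(p$b[3:4], c(2, hw, hw)), c(2, 3, 1)))
        go <- sig(z[, , 5:6] + aperm(array(p$b[5:6], c(2, hw, hw)), c(2, 3, 1)))
        gg <- tanh(z[, , 7:8] + aperm(array(p$b[7:8], c(2, hw, hw)), c(2, 3, 1)))
        C <- gf * C + gi * gg
        H <- go * tanh(C)
        outs[[t]] <- H
      }
      maps <- outs
    }
    top <- maps[[3]]
    # stride-2 pooling conv: evaluate full stride-1 same conv, subsample
    full <- naive_conv3(top, params$Wp, pad = 1L)
    hw <- dim(full)[1]
    pooled <- full[seq(1, hw, by = 2), seq(1, hw, by = 2), , drop = FALSE]
    pooled <- pooled + aperm(array(params$bp, c(2, dim(pooled)[1],
                                                dim(pooled)[2])), c(2, 3, 1))
    pooled <- pmax(pooled, 0)
    f <- as.vector(pooled)
    a1 <- pmax(drop(f %*% params$W1) + params$b1, 0)
    yhat <- drop(a1 %*% params$W2) + params$b2
    expect_equal(out[b, ], yhat, tolerance = 1e-10)
  }
})

test_that("forward passes are deterministic and input-sensitive", {
  cfg <- network_config(hidden_channels = 3L, cell_layers = 2L,
                        sequence_length = 4L, input_dim = c(12L, 12L),
                        k = 3L, pool_channels = 2L, fc_dim = 8L)
  params <- init_network(cfg, seed = 60)
  set.seed(61)
  X <- array(rnorm(12 * 12 * 4 * 2), c(12, 12, 4, 2))
  o1 <- rt4dcbct:::forward_convlstm(params, X, cfg)$out
  o2 <- rt4dcbct:::forward_convlstm(params, X, cfg)$out
  expect_identical(o1, o2)
  zeros <- array(0, c(12, 12, 4, 1))
  ones <- array(1, c(12, 12, 4, 1))
  oz <- rt4dcbct:::forward_convlstm(params, zeros, cfg)$out
  oo <- rt4dcbct:::forward_convlstm(params, ones, cfg)$out
  expect_gt(max(abs(oz - oo)), 0)
  # independent parameter copies give bit-identical outputs
  params2 <- init_network(cfg, seed = 60)
  expect_identical(o1, rt4dcbct:::forward_convlstm(params2, X, cfg)$out)
})

test_that("the forward pass reproduces its frozen reference output", {
  fix <- jsonlite::read_json(test_path("fixtures", "golden_forward.json"),
                             simplifyVector = TRUE)
  cfg <- do.call(network_config, fix$config)
  params <- init_network(cfg, seed = fix$seed)
  X <- array(fix$input, dim = fix$input_dim)
  out <- rt4dcbct:::forward_convlstm(params, X, cfg)$out
  expect_equal(as.numeric(out), fix$output, tolerance = 1e-6)
})

test_that("training reduces the loss on learnable synthetic data", {
  ds <- toy_dataset(n = 80L)
  cfg <- network_config(hidden_channels = 4L, cell_layers = 2L,
                        sequence_length = 3L, input_dim = c(16L, 16L),
                        k = 2L, pool_channels = 2L, fc_dim = 32L)
  tc <- training_config(epochs = 15L, wcoeff = c(2, 1) / 3, seed = 5L)
  m <- train_network(ds, cfg, tc)
  expect_lt(utils::tail(m$history$train_loss, 1),
            0.25 * m$history$train_loss[1])
  expect_equal(nrow(m$history), 15L)
  expect_error(train_network(list(sequences = ds$sequences[, , , 0,
                                                           drop = FALSE],
                                  labels = ds$labels[0, , drop = FALSE]),
                             cfg, tc), "empty|label")
})

test_that("seeded training runs are reproducible", {
  ds <- toy_dataset(n = 32L)
  cfg <- network_config(hidden_channels = 2L, cell_layers = 1L,
                        sequence_length = 3L, input_dim = c(16L, 16L),
                        k = 2L, pool_channels = 2L, fc_dim = 8L)
  tc <- training_config(epochs = 2L, wcoeff = c(1, 1) / 2, seed = 9L)
  m1 <- train_network(ds, cfg, tc)
  m2 <- train_network(ds, cfg, tc)
  expect_identical(m1$history, m2$history)
  expect_identical(m1$params$W2, m2$params$W2)
})

test_that("front-weighted loss favours first-coefficient accuracy", {
  ds <- toy_dataset(n = 96L, seed = 8L)
  cfg <- network_config(hidden_channels = 4L, cell_layers = 2L,
                        sequence_length = 3L, input_dim = c(16L, 16L),
                        k = 2L, pool_channels = 2L, fc_dim = 32L)
  val_mae1 <- function(wc) {
    tc <- training_config(epochs = 10L, wcoeff = wc, val_fraction = 0.25,
                          seed = 13L)
    m <- train_network(ds, cfg, tc)
    # standardized first-component MAE on the validation split
    set.seed(13L)
    n <- dim(ds$sequences)[4]
    perm <- sample.int(n)
    val <- perm[seq_len(round(0.25 * n))]
    pred <- predict_coefficients(m, ds$sequences[, , , val, drop = FALSE])
    mae(ds$labels[val, 1], pred[, 1]) / stats::sd(ds$labels[, 1])
  }
  expect_lte(val_mae1(c(2, 1) / 3), val_mae1(c(1, 1) / 2) + 1e-9)
})

test_that("convolutional pooling shrinks the head without losing convergence", {
  ds <- toy_dataset(n = 64L, seed = 12L)
  run <- function(pooling) {
    cfg <- network_config(hidden_channels = 3L, cell_layers = 1L,
                          sequence_length = 3L, input_dim = c(16L, 16L),
                          k = 2L, pool_channels = 2L, fc_dim = 16L,
                          pooling = pooling)
    tc <- training_config(epochs = 10L, wcoeff = c(1, 1) / 2, seed = 21L)
    train_network(ds, cfg, tc)
  }
  n_params <- function(m)
    sum(vapply(rt4dcbct:::flatten_params(m$params), length, numeric(1)))
  conv <- run("convolutional")
  none <- run("none")
  # the 2x down-sampling cuts the fully connected fan-in (here ~4x fewer
  # head parameters) while the weighted loss still converges well below its
  # starting value within the same epoch budget
  expect_lt(n_params(conv), 0.5 * n_params(none))
  expect_lt(utils::tail(conv$history$train_loss, 1),
            0.25 * conv$history$train_loss[1])
})

test_that("prediction de-standardizes with the stored scaler", {
  ds <- toy_dataset(n = 24L)
  cfg <- network_config(hidden_channels = 2L, cell_layers = 1L,
                        sequence_length = 3L, input_dim = c(16L, 16L),
                        k = 2L, pool_channels = 2L, fc_dim = 8L)
  tc <- training_config(epochs = 1L, wcoeff = c(1, 1) / 2, seed = 2L)
  m <- train_network(ds, cfg, tc)
  one <- ds$sequences[, , , 1]
  p1 <- predict_coefficients(m, one)
  p2 <- predict_coefficients(m, one)
  expect_identical(p1, p2)
  raw <- rt4dcbct:::forward_convlstm(m$params, array(one, c(dim(one), 1L)),
                                     m$net_config)$out
  expect_equal(as.numeric(p1),
               as.numeric(raw) * m$scaler$scale + m$scaler$center,
               tolerance = 1e-12)
  broken <- m; broken$scaler <- NULL
  expect_error(predict_coefficients(broken, one), "scaler")
  expect_error(predict_coefficients(m, ds$sequences[, , 1:2, 1]), "length")
})

test_that("per-image normalization yields zero mean and unit variance", {
  set.seed(70)
  img <- matrix(runif(64), 8)
  z <- normalize_drr(img)
  expect_equal(mean(z), 0, tolerance = 1e-12)
  expect_equal(stats::sd(as.numeric(z)), 1, tolerance = 1e-12)
  expect_true(all(normalize_drr(matrix(2, 4, 4)) == 0))
})
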