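# Convolutional machinery for the ConvLSTM.
#
# Feature maps are stored as (B * h * w) x C matrices (sample-major row
# blocks, image columns flattened column-major, channels as matrix columns).
# 3x3 convolutions are evaluated as im2col gathers followed by one BLAS GEMM
# against a (9 * Cin) x Cout weight matrix; the gather index tables are
# precomputed per (h, w, pad, stride, batch) and cached. Gradients w.r.t. a
# convolution input are obtained by scattering the patch gradients back
# through the same gather table (col2im), which handles any pad/stride.

.conv_cache <- new.env(parent = emptyenv())

conv_out_dim <- function(n, pad, stride) (n + 2L * pad - 3L) %/% stride + 1L

# Index tables for one (h, w, pad, stride, B) configuration.
conv_ctx <- function(h, w, pad, stride = 1L, B = 1L) {
  key <- paste(h, w, pad, stride, B, sep = "_")
  if (!is.null(.conv_cache[[key]])) return(.conv_cache[[key]])
  hp <- h + 2L * pad; wp <- w + 2L * pad
  ho <- conv_out_dim(h, pad, stride); wo <- conv_out_dim(w, pad, stride)
  npad <- hp * wp; nout <- ho * wo; npix <- h * w
  # interior placement of the unpadded image inside the padded one
  interior <- as.vector(outer((pad + 1L):(pad + h),
                              ((pad + 1L):(pad + w) - 1L) * hp, "+"))
  # gather table: idx0[r, k] = padded flat index feeding output pixel r,
  # kernel tap k (k = kr + 3 kc + 1, kr/kc in 0:2, row offset fastest)
  r0 <- (seq_len(ho) - 1L) * stride      # 0-based padded row of tap (0,0)
  c0 <- (seq_len(wo) - 1L) * stride
  base <- outer(r0 + 1L, c0 * hp, "+")   # nout as ho x wo
  idx0 <- matrix(0L, nout, 9L)
  for (kc in 0:2) for (kr in 0:2)
    idx0[, kr + 3L * kc + 1L] <- as.vector(base + kr + kc * hp)
  # batch replication
  if (B > 1L) {
    off <- rep((0:(B - 1L)) * npad, each = nout)
    idxB <- matrix(0L, B * nout, 9L)
    for (k in 1:9) idxB[, k] <- rep(idx0[, k], B) + off
    interiorB <- rep(interior, B) + rep((0:(B - 1L)) * npad, each = npix)
  } else {
    idxB <- idx0; interiorB <- interior
  }
  ctx <- list(h = h, w = w, pad = pad, stride = stride, B = B,
              hp = hp, wp = wp, ho = ho, wo = wo,
              npad = npad, nout = nout, npix = npix,
              idx = as.vector(idxB), idx0 = as.integer(as.vector(idxB) - 1L),
              interior = interiorB,
              interior0 = as.integer(interiorB - 1L), scatter = NULL)
  .conv_cache[[key]] <- ctx
  ctx
}

pad_maps <- function(X, ctx) {
  if (ctx$pad == 0L) return(X)
  .pad_maps_cpp(X, ctx$interior0, ctx$B * ctx$npad)
}

# im2col: (B*npix) x C maps -> (B*nout) x (9C) patch matrix.
conv_cols <- function(X, ctx) {
  Xp <- if (ctx$pad > 0L) pad_maps(X, ctx) else X
  .im2col_cpp(Xp, ctx$idx0, ctx$B * ctx$nout)
}

# Convolution: maps (B*npix) x Cin, weights (9 Cin) x Cout, optional bias.
conv_forward <- function(X, W, bias = NULL, ctx) {
  Z <- conv_cols(X, ctx) %*% W
  if (!is.null(bias)) Z <- Z + rep(bias, each = nrow(Z))
  Z
}

# Input gradient of a convolution: the patch gradients dZ %*% t(W) are
# scattered back through the same gather table the forward pass used
# (works for any pad/stride).
conv_backward_input <- function(dZ, W, ctx) {
  .col2im_cpp(dZ %*% t(W), ctx$idx0, ctx$B * ctx$npad, ctx$interior0)
}

sigmoid <- function(x) 1 / (1 + exp(-x))

#' One ConvLSTM cell update
#'
#' Applies the convolutional LSTM gate equations to one time step: with
#' input feature map `X_t` and previous state `(H_{t-1}, C_{t-1})`,
#' \deqn{i_t = \sigma(W_{xi} * X_t + W_{hi} * H_{t-1} + b_i)}
#' \deqn{f_t = \sigma(W_{xf} * X_t + W_{hf} * H_{t-1} + b_f)}
#' \deqn{o_t = \sigma(W_{xo} * X_t + W_{ho} * H_{t-1} + b_o)}
#' \deqn{G_t = \tanh(W_{xg} * X_t + W_{hg} * H_{t-1} + b_g)}
#' \deqn{C_t = f_t \circ C_{t-1} + i_t \circ G_t, \quad
#'       H_t = o_t \circ \tanh(C_t)}
#' where `*` is 3x3 convolution (stride 1) and the circle the Hadamard
#' product. The input path uses `pad_x` padding ("valid" shrinks the map by
#' 2); the recurrent path is always "same"-padded so the state keeps its
#' shape across time.
#'
#' @param X input array `(h, w, c_in)` (a 2-D matrix is taken as one
#'   channel).
#' @param state `NULL` (zero initial state) or list with arrays `H`, `C` of
#'   shape `(h', w', hidden)`.
#' @param params cell parameter list as produced by [init_network()]
#'   (`Wx` `(9 c_in) x (4 hidden)`, `Wh` `(9 hidden) x (4 hidden)`, `b`
#'   length `4 hidden`; gate column order i, f, o, g).
#' @param pad_x `"valid"` (default) or `"same"` padding of the input path.
#' @return list with updated arrays `H` and `C`, plus the gate maps `i`,
#'   `f`, `o`, `g`.
#' @export
convlstm_cell_step <- function(X, state = NULL, params, pad_x = c("valid", "same")) {
  pad_x <- match.arg(pad_x)
  if (is.matrix(X)) X <- array(X, c(dim(X), 1L))
  h <- dim(X)[1]; w <- dim(X)[2]; cin <- dim(X)[3]
  hidden <- length(params$b) / 4L
  if (nrow(params$Wx) != 9L * cin) stop("input channel mismatch")
  px <- if (pad_x == "valid") 0L else 1L
  ho <- conv_out_dim(h, px, 1L); wo <- conv_out_dim(w, px, 1L)
  ctx_x <- conv_ctx(h, w, px, 1L, 1L)
  ctx_h <- conv_ctx(ho, wo, 1L, 1L, 1L)
  Xm <- matrix(X, h * w, cin)
  if (is.null(state)) {
    Hm <- matrix(0, ho * wo, hidden); Cm <- matrix(0, ho * wo, hidden)
  } else {
    if (!all(dim(state$H)[1:2] == c(ho, wo))) stop("state shape mismatch")
    Hm <- matrix(state$H, ho * wo, hidden); Cm <- matrix(state$C, ho * wo, hidden)
  }
  Z <- conv_forward(Xm, params$Wx, NULL, ctx_x) +
    conv_forward(Hm, params$Wh, params$b, ctx_h)
  idx <- function(g) ((g - 1L) * hidden + 1L):(g * hidden)
  i_ <- sigmoid(Z[, idx(1), drop = FALSE])
  f_ <- sigmoid(Z[, idx(2), drop = FALSE])
  o_ <- sigmoid(Z[, idx(3), drop = FALSE])
  g_ <- tanh(Z[, idx(4), drop = FALSE])
  Cn <- f_ * Cm + i_ * g_
  Hn <- o_ * tanh(Cn)
  list(H = array(Hn, c(ho, wo, hidden)), C = array(Cn, c(ho, wo, hidden)),
       i = array(i_, c(ho, wo, hidden)), f = array(f_, c(ho, wo, hidden)),
       o = array(o_, c(ho, wo, hidden)), g = array(g_, c(ho, wo, hidden)))
}

glorot <- function(nr, nc) {
  l <- sqrt(6 / (nr + nc))
  matrix(stats::runif(nr * nc, -l, l), nr, nc)
}

#' Initialize ConvLSTM network parameters
#'
#' Glorot-uniform weights, zero biases except the forget-gate bias (set to
#' 1, the standard LSTM initialization that starts with an open memory
#' path).
#'
#' @param config a [network_config()].
#' @param seed integer RNG seed.
#' @return parameter list: per cell layer `Wx`, `Wh`, `b`; head `Wp`, `bp`
#'   (pooling convolution), `W1`, `b1`, `W2`, `b2` (fully connected pair).
#' @export
init_network <- function(config, seed = 1L) {
  set.seed(seed)
  hdim <- config$input_dim
  layers <- vector("list", config$cell_layers)
  cin <- 1L
  h <- hdim[1]; w <- hdim[2]
  H <- config$hidden_channels
  for (l in seq_len(config$cell_layers)) {
    layers[[l]] <- list(Wx = glorot(9L * cin, 4L * H),
                        Wh = glorot(9L * H, 4L * H),
                        b = c(rep(0, H), rep(1, H), rep(0, 2L * H)))
    h <- h - 2L; w <- w - 2L   # valid input path between layers
    cin <- H
  }
  if (identical(config$pooling, "none")) {
    flat <- h * w * H
    params <- list(layers = layers,
                   Wp = matrix(0, 0L, 0L), bp = numeric(0),
                   W1 = glorot(flat, config$fc_dim),
                   b1 = rep(0, config$fc_dim),
                   W2 = glorot(config$fc_dim, config$k),
                   b2 = rep(0, config$k))
    attr(params, "shapes") <- list(top = c(h, w), pooled = c(h, w), flat = flat)
    return(params)
  }
  P <- config$pool_channels
  hp <- conv_out_dim(h, 1L, 2L); wp <- conv_out_dim(w, 1L, 2L)
  flat <- hp * wp * P
  params <- list(layers = layers,
                 Wp = glorot(9L * H, P), bp = rep(0, P),
                 W1 = glorot(flat, config$fc_dim), b1 = rep(0, config$fc_dim),
                 W2 = glorot(config$fc_dim, config$k), b2 = rep(0, config$k))
  attr(params, "shapes") <- list(top = c(h, w), pooled = c(hp, wp), flat = flat)
  params
}

# Flatten (B*npix) x C maps to B x (npix*C) per-sample feature rows.
flatten_maps <- function(A, B, npix) {
  C <- ncol(A)
  dim(A) <- c(npix, B, C)
  A <- aperm(A, c(1, 3, 2))
  dim(A) <- c(npix * C, B)
  t(A)
}

unflatten_maps <- function(F_, B, npix) {
  C <- ncol(F_) / npix
  A <- t(F_)
  dim(A) <- c(npix, C, B)
  A <- aperm(A, c(1, 3, 2))
  dim(A) <- c(npix * B, C)
  A
}

# Full network forward pass over a batch.
#
# Xseq: array (h, w, T, B) of normalized DRR frames.
# Returns list(out = B x k, cache) - cache retained when `keep_cache`.
forward_convlstm <- function(params, Xseq, config, keep_cache = FALSE) {
  dims <- dim(Xseq)
  h0 <- dims[1]; w0 <- dims[2]; T_ <- dims[3]
  B <- if (length(dims) == 4L) dims[4] else 1L
  H <- config$hidden_channels
  L <- config$cell_layers
  # input maps per t: (B*npix0) x 1
  Xin <- vector("list", T_)
  Xarr <- aperm(array(Xseq, c(h0 * w0, T_, B)), c(1, 3, 2))  # npix x B x T
  for (t in seq_len(T_)) Xin[[t]] <- matrix(Xarr[, , t], h0 * w0 * B, 1L)
  layer_caches <- vector("list", L)
  h <- h0; w <- w0
  for (l in seq_len(L)) {
    ho <- h - 2L; wo <- w - 2L
    ctx_x <- conv_ctx(h, w, 0L, 1L, B)
    ctx_h <- conv_ctx(ho, wo, 1L, 1L, B)
    p <- params$layers[[l]]
    Hm <- matrix(0, B * ho * wo, H); Cm <- Hm
    steps <- vector("list", T_)
    Hs <- vector("list", T_)
    for (t in seq_len(T_)) {
      Zx <- conv_cols(Xin[[t]], ctx_x) %*% p$Wx
      Zh <- conv_cols(Hm, ctx_h) %*% p$Wh
      gs <- .lstm_gates_fwd_cpp(Zx, Zh, p$b, Cm)
      steps[[t]] <- list(i = gs$i, f = gs$f, o = gs$o, g = gs$g,
                         Cprev = Cm, tC = gs$tC)
      Cm <- gs$C
      Hm <- gs$H
      Hs[[t]] <- Hm
    }
    layer_caches[[l]] <- list(Xin = Xin, Hs = Hs, steps = steps,
                              h = h, w = w, ho = ho, wo = wo)
    Xin <- Hs
    h <- ho; w <- wo
  }
  # regression head on the final hidden map of the top layer
  top <- Xin[[T_]]                          # (B*npix_top) x H
  if (identical(config$pooling, "none")) {
    Zp <- NULL; Ap <- NULL
    F_ <- flatten_maps(top, B, h * w)
  } else {
    ctx_p <- conv_ctx(h, w, 1L, 2L, B)
    colsP <- conv_cols(top, ctx_p)
    Zp <- colsP %*% params$Wp + rep(params$bp, each = B * ctx_p$nout)
    Ap <- pmax(Zp, 0)
    F_ <- flatten_maps(Ap, B, ctx_p$nout)   # B x flat
  }
  Z1 <- F_ %*% params$W1 + rep(params$b1, each = B)
  A1 <- pmax(Z1, 0)
  out <- A1 %*% params$W2 + rep(params$b2, each = B)
  cache <- NULL
  if (keep_cache)
    cache <- list(layer_caches = layer_caches, top = top, Zp = Zp, Ap = Ap,
                  F_ = F_, Z1 = Z1, A1 = A1, B = B, T_ = T_,
                  h_top = h, w_top = w)
  list(out = out, cache = cache)
}

# Backward pass; dOut is B x k. Returns gradients with the same structure as
# the parameters.
backward_convlstm <- function(params, config, cache, dOut) {
  B <- cache$B; T_ <- cache$T_; H <- config$hidden_channels
  L <- config$cell_layers
  grads <- list(layers = vector("list", L))
  # head
  dW2 <- crossprod(cache$A1, dOut)
  db2 <- colSums(dOut)
  dA1 <- dOut %*% t(params$W2)
  dZ1 <- dA1 * (cache$Z1 > 0)
  dW1 <- crossprod(cache$F_, dZ1)
  db1 <- colSums(dZ1)
  dF <- dZ1 %*% t(params$W1)
  if (identical(config$pooling, "none")) {
    dTop <- unflatten_maps(dF, B, cache$h_top * cache$w_top)
    grads$Wp <- matrix(0, 0L, 0L); grads$bp <- numeric(0)
  } else {
    ctx_p <- conv_ctx(cache$h_top, cache$w_top, 1L, 2L, B)
    dAp <- unflatten_maps(dF, B, ctx_p$nout)
    dZp <- dAp * (cache$Zp > 0)
    colsP <- conv_cols(cache$top, ctx_p)
    dWp <- crossprod(colsP, dZp)
    dbp <- colSums(dZp)
    dTop <- conv_backward_input(dZp, params$Wp, ctx_p)
    grads$Wp <- dWp; grads$bp <- dbp
  }
  grads$W1 <- dW1; grads$b1 <- db1; grads$W2 <- dW2; grads$b2 <- db2
  # dH arriving at the top layer: only the final step feeds the head
  dH_upper <- vector("list", T_)
  zero_top <- matrix(0, nrow(dTop), ncol(dTop))
  for (t in seq_len(T_)) dH_upper[[t]] <- zero_top
  dH_upper[[T_]] <- dTop
  for (l in L:1) {
    lc <- cache$layer_caches[[l]]
    p <- params$layers[[l]]
    ctx_x <- conv_ctx(lc$h, lc$w, 0L, 1L, B)
    ctx_h <- conv_ctx(lc$ho, lc$wo, 1L, 1L, B)
    dWx <- matrix(0, nrow(p$Wx), ncol(p$Wx))
    dWh <- matrix(0, nrow(p$Wh), ncol(p$Wh))
    db <- numeric(length(p$b))
    dH_rec <- NULL; dC_rec <- matrix(0, 0L, 0L)
    dX_lower <- vector("list", T_)
    for (t in T_:1) {
      st <- lc$steps[[t]]
      dHt <- dH_upper[[t]]
      if (!is.null(dH_rec)) dHt <- dHt + dH_rec
      res <- .lstm_gates_bwd_cpp(dHt, dC_rec, st$i, st$f, st$o, st$g,
                                 st$Cprev, st$tC)
      dZ <- res$dZ
      dC_rec <- res$dC_prev
      Hprev <- if (t == 1L) matrix(0, B * ctx_h$npix, H) else lc$Hs[[t - 1L]]
      dWx <- dWx + crossprod(conv_cols(lc$Xin[[t]], ctx_x), dZ)
      dWh <- dWh + crossprod(conv_cols(Hprev, ctx_h), dZ)
      db <- db + colSums(dZ)
      dH_rec <- conv_backward_input(dZ, p$Wh, ctx_h)
      if (l > 1L) dX_lower[[t]] <- conv_backward_input(dZ, p$Wx, ctx_x)
    }
    grads$layers[[l]] <- list(Wx = dWx, Wh = dWh, b = db)
    if (l > 1L) dH_upper <- dX_lower
  }
  grads
}
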