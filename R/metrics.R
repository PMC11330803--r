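#' Coefficient and image fidelity metrics
#'
#' Quantification suite for predicted PCA coefficients and reconstructed
#' images/volumes: mean absolute error (MAE), zero-normalized cross
#' correlation (NCC), structural similarity (SSIM), peak signal-to-noise
#' ratio (PSNR), root mean squared error (RMSE) and mean absolute percentage
#' error (MAPE).
#'
#' @param y,y_hat numeric vectors of equal length (reference, prediction).
#' @return a single numeric value.
#' @name metrics
NULL

#' @describeIn metrics Mean absolute error `mean(|y_hat - y|)`.
#' @export
mae <- function(y, y_hat) {
  if (length(y) != length(y_hat)) stop("length mismatch")
  mean(abs(as.numeric(y_hat) - as.numeric(y)))
}

#' @describeIn metrics Zero-normalized cross correlation of two equally shaped
#'   images/volumes, in `[-1, 1]`. Both inputs must be non-constant.
#' @param S,T_ numeric arrays/matrices of identical shape.
#' @export
ncc <- function(S, T_) {
  if (!isTRUE(all.equal(dim1(S), dim1(T_)))) stop("shape mismatch")
  s <- as.numeric(S) - mean(S)
  t_ <- as.numeric(T_) - mean(T_)
  ds <- sqrt(sum(s^2)); dt <- sqrt(sum(t_^2))
  if (ds == 0 || dt == 0) stop("NCC undefined for a constant image")
  sum(s * t_) / (ds * dt)
}

dim1 <- function(x) if (is.null(dim(x))) length(x) else dim(x)

# Discrete 1-D Gaussian taps as used for the SSIM window: radius
# `int(truncate * sigma + 0.5)`, samples of exp(-x^2 / (2 sigma^2)),
# normalized to sum 1.
gaussian_taps <- function(sigma = 1.5, truncate = 3.5) {
  r <- as.integer(truncate * sigma + 0.5)
  x <- (-r):r
  k <- exp(-0.5 * (x / sigma)^2)
  k / sum(k)
}

# Valid-region separable Gaussian filtering of a matrix.
gauss_filter_valid <- function(m, taps) {
  r <- (length(taps) - 1L) %/% 2L
  nr <- nrow(m); nc <- ncol(m)
  if (nr < length(taps) || nc < length(taps))
    stop("image smaller than the SSIM window")
  # filter along rows (dimension 1)
  out1 <- matrix(0, nr - 2L * r, nc)
  for (j in seq_along(taps))
    out1 <- out1 + taps[j] * m[j:(nr - 2L * r + j - 1L), , drop = FALSE]
  out <- matrix(0, nr - 2L * r, nc - 2L * r)
  for (j in seq_along(taps))
    out <- out + taps[j] * out1[, j:(nc - 2L * r + j - 1L), drop = FALSE]
  out
}

#' @describeIn metrics Single-scale structural similarity index with a
#'   Gaussian window (sigma 1.5, 11 x 11 support), `C1 = (0.01 L)^2`,
#'   `C2 = (0.03 L)^2` for data range `L`. 3-D inputs are reduced to their
#'   mid-coronal slice first via [mid_slice()] when `slice = TRUE`.
#' @param data_range dynamic range `L` of the data; defaults to
#'   `max(S) - min(S)` of the reference.
#' @export
ssim <- function(S, T_, data_range = NULL) {
  S <- as.matrix2d(S); T_ <- as.matrix2d(T_)
  if (!isTRUE(all.equal(dim(S), dim(T_)))) stop("shape mismatch")
  if (is.null(data_range)) data_range <- diff(range(S))
  if (data_range <= 0) stop("data_range must be positive")
  taps <- gaussian_taps()
  C1 <- (0.01 * data_range)^2
  C2 <- (0.03 * data_range)^2
  ux <- gauss_filter_valid(S, taps)
  uy <- gauss_filter_valid(T_, taps)
  uxx <- gauss_filter_valid(S * S, taps)
  uyy <- gauss_filter_valid(T_ * T_, taps)
  uxy <- gauss_filter_valid(S * T_, taps)
  vx <- uxx - ux^2; vy <- uyy - uy^2; vxy <- uxy - ux * uy
  smap <- ((2 * ux * uy + C1) * (2 * vxy + C2)) /
          ((ux^2 + uy^2 + C1) * (vx + vy + C2))
  mean(smap)
}

as.matrix2d <- function(x) {
  if (inherits(x, "volume3d")) x <- x$values
  if (is.matrix(x)) return(x)
  if (is.array(x) && length(dim(x)) == 3L) return(mid_slice(x))
  stop("expected a matrix or 3-D array")
}

#' Mid-coronal slice of a volume
#'
#' Extracts the central slice along the anterior-posterior (y) axis, the
#' plane on which planar image metrics are evaluated by default.
#'
#' @param x a [volume3d()] or 3-D array.
#' @param plane `"coronal"` (fix y), `"sagittal"` (fix x) or `"axial"`
#'   (fix z).
#' @return a matrix.
#' @export
mid_slice <- function(x, plane = c("coronal", "sagittal", "axial")) {
  plane <- match.arg(plane)
  a <- if (inherits(x, "volume3d")) x$values else x
  d <- dim(a)
  switch(plane,
         coronal  = a[, (d[2] + 1L) %/% 2L, ],
         sagittal = a[(d[1] + 1L) %/% 2L, , ],
         axial    = a[, , (d[3] + 1L) %/% 2L])
}

#' @describeIn metrics Peak signal-to-noise ratio `10 log10(MAX^2 / MSE)` in
#'   dB; identical inputs give `Inf`.
#' @param max_value peak value `MAX`; defaults to `max(S)` of the reference.
#' @export
psnr <- function(S, T_, max_value = NULL) {
  if (!isTRUE(all.equal(dim1(S), dim1(T_)))) stop("shape mismatch")
  if (is.null(max_value)) max_value <- max(S)
  mse <- mean((as.numeric(S) - as.numeric(T_))^2)
  if (mse == 0) return(Inf)
  10 * log10(max_value^2 / mse)
}

#' @describeIn metrics Root mean squared error.
#' @export
rmse <- function(S, T_) {
  if (!isTRUE(all.equal(dim1(S), dim1(T_)))) stop("shape mismatch")
  sqrt(mean((as.numeric(S) - as.numeric(T_))^2))
}

#' @describeIn metrics Mean absolute percentage error
#'   `mean(|S - T| / |T|)` over entries where the reference `T` is bounded
#'   away from zero (`|T| > eps`, `eps = 1e-6 * max(|T|)`); the number of
#'   masked entries is attached as attribute `"n_masked"`.
#' @export
mape <- function(S, T_) {
  if (length(S) != length(T_)) stop("length mismatch")
  S <- as.numeric(S); T_ <- as.numeric(T_)
  eps <- 1e-6 * max(abs(T_))
  keep <- abs(T_) > eps
  if (!any(keep)) stop("all reference entries are (near-)zero; MAPE undefined")
  out <- mean(abs(S[keep] - T_[keep]) / abs(T_[keep]))
  attr(out, "n_masked") <- sum(!keep)
  out
}

#' Full metric report for a reconstruction
#'
#' Computes all six metrics between a reconstructed and a ground-truth
#' volume: MAE/RMSE/MAPE voxelwise on the evaluation plane, NCC over the full
#' volume, and SSIM/PSNR on the mid-plane slice.
#'
#' @param recon,truth [volume3d()] objects on the same grid.
#' @param plane evaluation plane for the slice metrics, see [mid_slice()].
#' @return a list with entries `mae`, `ncc`, `ssim`, `psnr`, `rmse`, `mape`
#'   and `plane`.
#' @export
metric_report <- function(recon, truth, plane = "coronal") {
  rs <- mid_slice(recon, plane); ts <- mid_slice(truth, plane)
  list(mae  = mae(ts, rs),
       ncc  = ncc(truth$values, recon$values),
       ssim = ssim(ts, rs, data_range = diff(range(ts))),
       psnr = psnr(ts, rs, max_value = max(ts)),
       rmse = rmse(ts, rs),
       mape = as.numeric(mape(rs, ts)),
       plane = plane)
}
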