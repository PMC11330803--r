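#' Fit a PCA motion model to a stack of deformation fields
#'
#' Mean-centered principal component analysis of flattened DVFs: each field
#' of length `3 N_voxel` is one observation, the model stores the mean field,
#' the orthonormal eigenvector fields ordered by decreasing eigenvalue, and
#' the full explained-variance spectrum. A field is then represented as
#' `mean + sum_j q_j p_j` with the first `k` coefficients `q_j` (default
#' `k = 3`, which for respiratory DVF stacks already captures most of the
#' motion information).
#'
#' Computed via thin SVD of the mean-centered `3N x P` matrix rather than the
#' `3N x 3N` covariance; the results are identical and the cost scales with
#' the number of phases `P`, not the voxel count.
#'
#' @param dvfs list of [dvf_volume()] objects on identical grids (>= 2).
#' @param k truncation order (>= 1); values above the rank of the centered
#'   stack are clamped with a warning.
#' @return object of class `pca_motion_model` with fields `mean_dvf`
#'   (numeric 3N vector), `basis` (3N x r matrix of orthonormal
#'   eigenvectors), `explained_ratios` (length r, non-increasing, summing to
#'   1), `sdev`, `k`, and `grid` metadata.
#' @export
fit_pca <- function(dvfs, k = 3L) {
  if (length(dvfs) < 2L) stop("need at least 2 DVFs")
  if (k < 1L) stop("k must be >= 1")
  g1 <- dvfs[[1]]
  if (!all(vapply(dvfs, function(d) same_grid(d, g1), logical(1))))
    stop("all DVFs must share one grid")
  X <- vapply(dvfs, dvf_as_vector, numeric(length(dvf_as_vector(g1))))
  mean_dvf <- rowMeans(X)
  Xc <- X - mean_dvf
  sv <- svd(Xc, nu = ncol(Xc), nv = 0)
  tol <- max(sv$d) * 1e-10
  r <- sum(sv$d > tol)
  if (r == 0L) stop("degenerate stack: all DVFs equal their mean")
  if (k > r) {
    warning(sprintf("k = %d exceeds the rank %d of the centered stack; clamped", k, r))
    k <- r
  }
  lam <- sv$d[seq_len(r)]^2
  structure(list(mean_dvf = mean_dvf,
                 basis = sv$u[, seq_len(r), drop = FALSE],
                 explained_ratios = lam / sum(lam),
                 sdev = sv$d[seq_len(r)] / sqrt(max(1, ncol(X) - 1)),
                 k = as.integer(k),
                 n_train = ncol(X),
                 grid = list(dims = grid_dims(g1), spacing = g1$spacing,
                             origin = g1$origin)),
            class = "pca_motion_model")
}

#' @export
print.pca_motion_model <- function(x, ...) {
  cat(sprintf("<pca_motion_model> %d modes (k = %d), grid %s, first ratios: %s\n",
              length(x$explained_ratios), x$k,
              paste(x$grid$dims, collapse = "x"),
              paste(sprintf("%.1f%%", 100 * utils::head(x$explained_ratios, 3)),
                    collapse = ", ")))
  invisible(x)
}

#' Cumulative information curve of a PCA motion model
#'
#' Cumulative and incremental explained-variance percentages per number of
#' retained components, the standard way to choose the truncation order.
#' Values are unrounded; round to two decimals for reporting.
#'
#' @param model a fitted [fit_pca()] model.
#' @return data.frame with columns `n_components`, `cumulative_percent`,
#'   `increment_percent`.
#' @export
information_curve <- function(model) {
  cum <- 100 * cumsum(model$explained_ratios)
  data.frame(n_components = seq_along(cum),
             cumulative_percent = cum,
             increment_percent = c(cum[1], diff(cum)))
}

#' Synthesize a deformation field from PCA coefficients
#'
#' Evaluates `mean + sum_{j<=k} q_j p_j` and reshapes to the model grid.
#'
#' @param model a fitted [fit_pca()] model.
#' @param q numeric coefficient vector of length `model$k`.
#' @param phase optional phase tag for the result.
#' @return a [dvf_volume()].
#' @export
synthesize_dvf <- function(model, q, phase = NA_integer_) {
  q <- as.numeric(q)
  if (length(q) != model$k) stop("coefficient vector must have length k")
  if (any(!is.finite(q))) stop("coefficients must be finite")
  v <- model$mean_dvf + drop(model$basis[, seq_len(model$k), drop = FALSE] %*% q)
  dvf_volume(array(v, dim = c(model$grid$dims, 3L)),
             spacing = model$grid$spacing, origin = model$grid$origin,
             phase = phase)
}

#' Project a deformation field onto the PCA basis
#'
#' Least-squares optimal coefficients under orthonormality:
#' `q_j = p_j . (dvf - mean)`.
#'
#' @param model a fitted [fit_pca()] model.
#' @param dvf a [dvf_volume()] on the model grid.
#' @param k number of coefficients to return (default `model$k`).
#' @return numeric coefficient vector of length `k`.
#' @export
project_dvf <- function(model, dvf, k = model$k) {
  if (!isTRUE(all.equal(grid_dims(dvf), model$grid$dims)) ||
      !isTRUE(all.equal(dvf$spacing, model$grid$spacing)))
    stop("DVF grid does not match the model grid")
  k <- min(k, ncol(model$basis))
  drop(crossprod(model$basis[, seq_len(k), drop = FALSE],
                 dvf_as_vector(dvf) - model$mean_dvf))
}

#' Random coefficient sampling with amplitude expansion
#'
#' Draws training coefficient vectors independently and uniformly per
#' component over the per-component range of the source phases, enlarged by
#' `expansion` (default 15%) below the minimum and above the maximum, so the
#' simulated respiration covers slightly more than the average motion range
#' observed in the planning 4D-CT.
#'
#' @param model a fitted [fit_pca()] model.
#' @param phases matrix of per-phase coefficients (`n_phases x k`) as
#'   obtained by [project_dvf()] on the training DVFs, or a list of
#'   coefficient vectors.
#' @param n_samples number of coefficient sets to draw (default 900).
#' @param expansion fractional range expansion `e` (default 0.15): component
#'   `j` is drawn from `[min_j - e R_j, max_j + e R_j]`, `R_j = max_j - min_j`.
#' @param seed integer seed for reproducible sampling.
#' @return `n_samples x k` matrix of coefficients.
#' @export
sample_coefficients <- function(model, phases, n_samples = 900L,
                                expansion = 0.15, seed = 1L) {
  if (is.list(phases)) phases <- do.call(rbind, phases)
  phases <- as.matrix(phases)
  if (ncol(phases) != model$k) stop("phases must have k columns")
  if (n_samples < 1L) stop("n_samples must be >= 1")
  if (expansion < 0) stop("expansion must be >= 0")
  lo <- apply(phases, 2, min); hi <- apply(phases, 2, max)
  R <- hi - lo
  if (all(R == 0)) stop("degenerate motion: all phases share one coefficient vector")
  lo <- lo - expansion * R
  hi <- hi + expansion * R
  set.seed(seed)
  q <- matrix(stats::runif(n_samples * model$k), n_samples, model$k)
  q <- sweep(sweep(q, 2, hi - lo, "*"), 2, lo, "+")
  colnames(q) <- paste0("q", seq_len(model$k))
  q
}

#' Periodic coefficient trajectory through the phase coefficients
#'
#' Interpolates the per-phase PCA coefficients periodically over the
#' breathing cycle, giving a continuous coefficient path `q(t)` for
#' arbitrary (fractional) phase positions. Used to build temporally ordered
#' DRR training sequences.
#'
#' @param phases `n_phases x k` coefficient matrix, row `i` = phase `i - 1`.
#' @return function `q(t)` mapping a vector of phase positions (cycle units,
#'   period `n_phases`) to a `length(t) x k` coefficient matrix.
#' @export
coefficient_trajectory <- function(phases) {
  phases <- as.matrix(phases)
  n <- nrow(phases); k <- ncol(phases)
  xs <- 0:n  # close the cycle
  splines <- lapply(seq_len(k), function(j) {
    ys <- c(phases[, j], phases[1, j])
    stats::splinefun(xs, ys, method = "periodic")
  })
  function(t) {
    tm <- t %% n
    out <- vapply(splines, function(f) f(tm), numeric(length(t)))
    matrix(out, nrow = length(t), ncol = k)
  }
}

#' Serialize / restore a PCA motion model
#'
#' Stores the mean field, eigenvector basis, spectrum and grid metadata in a
#' single RDS archive.
#'
#' @param model a [fit_pca()] model.
#' @param path file path (conventionally `.rds`).
#' @return `save_motion_model()` returns `path` invisibly;
#'   `load_motion_model()` the restored model.
#' @export
save_motion_model <- function(model, path) {
  saveRDS(unclass(model), path)
  invisible(path)
}

#' @rdname save_motion_model
#' @export
load_motion_model <- function(path) {
  structure(readRDS(path), class = "pca_motion_model")
}

#' Write sampled coefficients as CSV
#'
#' @param q coefficient matrix from [sample_coefficients()].
#' @param path output CSV path with columns `sample_id`, `q1`, `q2`, ...
#' @export
write_coefficients_csv <- function(q, path) {
  df <- data.frame(sample_id = seq_len(nrow(q)), q)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
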