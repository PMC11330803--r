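#' Scalar attenuation volume on a regular grid
#'
#' A `volume3d` holds a 3-D array of linear attenuation coefficients
#' (mm^-1) together with the voxel spacing and the world coordinate of the
#' first voxel centre. Voxel centres live at `origin + (index - 1) * spacing`
#' along each axis (x = left-right, y = anterior-posterior, z =
#' inferior-superior).
#'
#' @param values numeric 3-D array of attenuation values (mm^-1), finite and
#'   non-negative.
#' @param spacing numeric length-3 vector, mm per voxel along (x, y, z).
#' @param origin numeric length-3 vector, world position (mm) of the centre of
#'   voxel (1, 1, 1).
#' @return An object of class `volume3d`.
#' @export
volume3d <- function(values, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  if (!is.array(values) || length(dim(values)) != 3L)
    stop("`values` must be a 3-D array")
  if (any(!is.finite(values))) stop("volume values must be finite")
  if (any(values < 0)) stop("attenuation values must be non-negative")
  spacing <- as.numeric(spacing); origin <- as.numeric(origin)
  if (length(spacing) != 3L || any(spacing <= 0)) stop("invalid spacing")
  if (length(origin) != 3L) stop("invalid origin")
  structure(list(values = values, spacing = spacing, origin = origin),
            class = "volume3d")
}

#' @export
print.volume3d <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<volume3d> %d x %d x %d voxels, spacing %s mm, range [%.4g, %.4g] mm^-1\n",
              d[1], d[2], d[3], paste(format(x$spacing), collapse = " x "),
              min(x$values), max(x$values)))
  invisible(x)
}

#' Per-voxel deformation vector field
#'
#' A `dvf_volume` stores one 3-component displacement (mm) per voxel, in the
#' pull-back convention: warping a volume with the field samples the input at
#' `x + d(x)` to produce the output value at `x`. Flattened with
#' [as.vector()]/[dvf_as_vector()] the field has length `3 * prod(grid dims)`.
#'
#' @param displacement numeric 4-D array `[nx, ny, nz, 3]` of displacements in
#'   mm (components ordered x, y, z).
#' @param spacing,origin grid metadata as in [volume3d()].
#' @param phase optional integer phase tag (0 = reference phase).
#' @return An object of class `dvf_volume`.
#' @export
dvf_volume <- function(displacement, spacing = c(1, 1, 1), origin = c(0, 0, 0),
                       phase = NA_integer_) {
  if (!is.array(displacement) || length(dim(displacement)) != 4L ||
      dim(displacement)[4] != 3L)
    stop("`displacement` must be an [nx, ny, nz, 3] array")
  if (any(!is.finite(displacement))) stop("displacements must be finite")
  structure(list(displacement = displacement, spacing = as.numeric(spacing),
                 origin = as.numeric(origin), phase = phase),
            class = "dvf_volume")
}

#' @export
print.dvf_volume <- function(x, ...) {
  d <- dim(x$displacement)
  mags <- sqrt(rowSums(matrix(x$displacement, ncol = 3L)^2))
  cat(sprintf("<dvf_volume> %d x %d x %d voxels, phase %s, |d| max %.3f mm\n",
              d[1], d[2], d[3], format(x$phase), max(mags)))
  invisible(x)
}

#' Flatten a DVF to a single vector
#'
#' Stacks the three displacement components voxel-grid first (x block, then y,
#' then z), giving a vector of length `3 * N_voxel` as used by the PCA motion
#' model.
#'
#' @param dvf a [dvf_volume()].
#' @return numeric vector of length `3 * prod(grid dims)`.
#' @export
dvf_as_vector <- function(dvf) as.vector(dvf$displacement)

grid_dims <- function(x) {
  if (inherits(x, "volume3d")) dim(x$values) else dim(x$displacement)[1:3]
}

same_grid <- function(a, b) {
  isTRUE(all.equal(grid_dims(a), grid_dims(b))) &&
    isTRUE(all.equal(a$spacing, b$spacing)) &&
    isTRUE(all.equal(a$origin, b$origin))
}

#' World coordinates of all voxel centres
#'
#' @param vol a [volume3d()] or [dvf_volume()].
#' @return an `N x 3` matrix of world coordinates in mm, voxel order matching
#'   the flattened array (x index fastest).
#' @export
voxel_centers <- function(vol) {
  d <- grid_dims(vol)
  xs <- vol$origin[1] + (seq_len(d[1]) - 1) * vol$spacing[1]
  ys <- vol$origin[2] + (seq_len(d[2]) - 1) * vol$spacing[2]
  zs <- vol$origin[3] + (seq_len(d[3]) - 1) * vol$spacing[3]
  cbind(rep(xs, times = d[2] * d[3]),
        rep(rep(ys, each = d[1]), times = d[3]),
        rep(zs, each = d[1] * d[2]))
}

# Trilinear interpolation of `values` (3-D array) at continuous 1-based voxel
# index coordinates `ci` (N x 3). Points outside the grid return `fill`.
trilinear_sample <- function(values, ci, fill = 0) {
  d <- dim(values)
  i0 <- floor(ci)
  fr <- ci - i0
  # clamp so that i0 and i0+1 are valid; record which points were inside
  # (with a sub-voxel tolerance so round-off at the faces stays inside)
  eps <- 1e-9
  inside <- ci[, 1] >= 1 - eps & ci[, 1] <= d[1] + eps &
            ci[, 2] >= 1 - eps & ci[, 2] <= d[2] + eps &
            ci[, 3] >= 1 - eps & ci[, 3] <= d[3] + eps
  i0[, 1] <- pmin.int(pmax.int(i0[, 1], 1L), d[1] - 1L)
  i0[, 2] <- pmin.int(pmax.int(i0[, 2], 1L), d[2] - 1L)
  i0[, 3] <- pmin.int(pmax.int(i0[, 3], 1L), d[3] - 1L)
  fr <- ci - i0
  fr[fr < 0] <- 0; fr[fr > 1] <- 1
  sx <- d[1]; sxy <- d[1] * d[2]
  base <- (i0[, 1]) + (i0[, 2] - 1) * sx + (i0[, 3] - 1) * sxy
  v <- as.vector(values)
  fx <- fr[, 1]; fy <- fr[, 2]; fz <- fr[, 3]
  gx <- 1 - fx; gy <- 1 - fy; gz <- 1 - fz
  out <- v[base]                 * gx * gy * gz +
         v[base + 1]             * fx * gy * gz +
         v[base + sx]            * gx * fy * gz +
         v[base + sx + 1]        * fx * fy * gz +
         v[base + sxy]           * gx * gy * fz +
         v[base + sxy + 1]       * fx * gy * fz +
         v[base + sxy + sx]      * gx * fy * fz +
         v[base + sxy + sx + 1]  * fx * fy * fz
  out[!inside] <- fill
  out
}

# Sample a volume3d at arbitrary world points (N x 3 matrix, mm).
sample_volume <- function(vol, pts, fill = 0) {
  ci <- sweep(sweep(pts, 2, vol$origin, "-"), 2, vol$spacing, "/") + 1
  trilinear_sample(vol$values, ci, fill = fill)
}

#' Warp a volume with a deformation vector field
#'
#' Pull-back trilinear resampling: the output value at voxel centre `x` is the
#' input volume interpolated at `x + d(x)`. Samples falling outside the input
#' grid are filled with 0.
#'
#' @param vol a [volume3d()].
#' @param dvf a [dvf_volume()] on the same grid.
#' @return a [volume3d()] on the same grid.
#' @export
warp_volume <- function(vol, dvf) {
  if (!same_grid(vol, dvf)) stop("volume and DVF grids do not match")
  d <- grid_dims(vol)
  n <- prod(d)
  disp <- matrix(dvf$displacement, nrow = n, ncol = 3L)
  pts <- voxel_centers(vol) + disp
  out <- sample_volume(vol, pts, fill = 0)
  out[out < 0] <- 0  # guard tiny negative interpolation round-off
  volume3d(array(out, dim = d), spacing = vol$spacing, origin = vol$origin)
}

#' Read/write volumes and DVFs as NIfTI
#'
#' Volumes are written as 3-D NIfTI images, DVFs as 4-D images whose fourth
#' dimension holds the (x, y, z) displacement components in mm. Voxel spacing
#' is stored in the NIfTI header; the world origin is kept in the sform
#' translation.
#'
#' @param vol a [volume3d()] or [dvf_volume()].
#' @param path output path (`.nii` or `.nii.gz`).
#' @return `write_nifti_volume()` returns `path` invisibly;
#'   `read_nifti_volume()` a [volume3d()]; `read_nifti_dvf()` a
#'   [dvf_volume()].
#' @export
write_nifti_volume <- function(vol, path) {
  arr <- if (inherits(vol, "volume3d")) vol$values else vol$displacement
  img <- RNifti::asNifti(arr)
  pd <- RNifti::pixdim(img)
  pd[1:3] <- vol$spacing
  RNifti::pixdim(img) <- pd
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_nifti_volume
#' @export
read_nifti_volume <- function(path) {
  img <- RNifti::readNifti(path)
  arr <- array(as.numeric(img), dim = dim(img))
  volume3d(arr, spacing = RNifti::pixdim(img)[1:3])
}

#' @rdname write_nifti_volume
#' @param phase phase tag attached to the DVF read back.
#' @export
read_nifti_dvf <- function(path, phase = NA_integer_) {
  img <- RNifti::readNifti(path)
  arr <- array(as.numeric(img), dim = dim(img))
  dvf_volume(arr, spacing = RNifti::pixdim(img)[1:3], phase = phase)
}
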