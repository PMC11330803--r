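#' Cone-beam acquisition geometry at a fixed gantry angle
#'
#' The source rotates about the volume z (superior-inferior) axis. At gantry
#' angle 0 the source sits on the +y axis at distance `sad` from the
#' isocenter and the flat-panel detector on the opposite side at
#' `sdd - sad`, with detector u along +x and v along +z. The single-angle
#' geometry reflects the acquisition model in which every training DRR and
#' every online projection is measured at one fixed angle.
#'
#' @param sad source-to-axis (isocenter) distance, mm.
#' @param sdd source-to-detector distance, mm (`sdd > sad > 0`).
#' @param gantry_deg gantry rotation about z, degrees.
#' @param detector_size integer `(n_u, n_v)` pixels.
#' @param pixel_pitch detector pixel size, mm.
#' @param isocenter world isocenter (mm); `NULL` = centre of the projected
#'   volume, resolved at projection time.
#' @return object of class `cone_beam_geometry`.
#' @export
cone_beam_geometry <- function(sad = 1000, sdd = 1500, gantry_deg = 0,
                               detector_size = c(128L, 128L),
                               pixel_pitch = 2, isocenter = NULL) {
  if (!(sdd > sad && sad > 0)) stop("geometry requires SDD > SAD > 0")
  if (pixel_pitch <= 0) stop("pixel_pitch must be positive")
  detector_size <- as.integer(detector_size)
  if (length(detector_size) != 2L || any(detector_size < 1L))
    stop("detector_size must be two positive integers")
  structure(list(sad = sad, sdd = sdd, gantry_deg = gantry_deg,
                 detector_size = detector_size, pixel_pitch = pixel_pitch,
                 isocenter = isocenter),
            class = "cone_beam_geometry")
}

geometry_frame <- function(geom, vol = NULL) {
  iso <- geom$isocenter
  if (is.null(iso)) {
    if (is.null(vol)) stop("geometry has no isocenter and no volume was given")
    iso <- vol$origin + (grid_dims(vol) - 1) * vol$spacing / 2
  }
  g <- geom$gantry_deg * pi / 180
  dirn <- c(sin(g), cos(g), 0)        # isocenter -> source
  u_axis <- c(cos(g), -sin(g), 0)
  v_axis <- c(0, 0, 1)
  list(iso = iso,
       source = iso + geom$sad * dirn,
       det_center = iso - (geom$sdd - geom$sad) * dirn,
       u_axis = u_axis, v_axis = v_axis)
}

detector_pixel_positions <- function(geom, frame) {
  nu <- geom$detector_size[1]; nv <- geom$detector_size[2]
  us <- (seq_len(nu) - (nu + 1) / 2) * geom$pixel_pitch
  vs <- (seq_len(nv) - (nv + 1) / 2) * geom$pixel_pitch
  uu <- rep(us, times = nv); vv <- rep(vs, each = nu)
  list(x = frame$det_center[1] + uu * frame$u_axis[1] + vv * frame$v_axis[1],
       y = frame$det_center[2] + uu * frame$u_axis[2] + vv * frame$v_axis[2],
       z = frame$det_center[3] + uu * frame$u_axis[3] + vv * frame$v_axis[3])
}

#' Forward projection: digitally reconstructed radiograph
#'
#' Computes, for every detector pixel, the exact radiological path integral
#' of the volume from the X-ray source to the pixel centre using Siddon's
#' incremental ray traversal (piecewise-constant voxels, exact intersection
#' lengths). The result is the noise-free line integral image
#' `p_n(u, v)` (dimensionless).
#'
#' @param vol a [volume3d()].
#' @param geom a [cone_beam_geometry()].
#' @return object of class `drr_image`: list with `values` (`n_u x n_v`
#'   matrix), `geometry`, `noisy` flag.
#' @export
forward_project <- function(vol, geom) {
  frame <- geometry_frame(geom, vol)
  # footprint check: project the volume box corners onto the detector
  d <- grid_dims(vol)
  crn <- as.matrix(expand.grid(x = c(vol$origin[1] - vol$spacing[1] / 2,
                                     vol$origin[1] + (d[1] - 0.5) * vol$spacing[1]),
                               y = c(vol$origin[2] - vol$spacing[2] / 2,
                                     vol$origin[2] + (d[2] - 0.5) * vol$spacing[2]),
                               z = c(vol$origin[3] - vol$spacing[3] / 2,
                                     vol$origin[3] + (d[3] - 0.5) * vol$spacing[3])))
  ax <- (frame$det_center - frame$source) / geom$sdd
  rel <- sweep(crn, 2, frame$source, "-")
  tproj <- geom$sdd / as.numeric(rel %*% ax)
  hit <- sweep(rel * tproj, 2, frame$source + 0, "+")  # points on detector plane
  hit <- sweep(hit, 2, frame$det_center, "-")
  ucoord <- as.numeric(hit %*% frame$u_axis)
  vcoord <- as.numeric(hit %*% frame$v_axis)
  half_u <- geom$detector_size[1] * geom$pixel_pitch / 2
  half_v <- geom$detector_size[2] * geom$pixel_pitch / 2
  if (any(abs(ucoord) > half_u) || any(abs(vcoord) > half_v))
    warning("detector does not cover the full projected volume footprint")
  pix <- detector_pixel_positions(geom, frame)
  p <- .siddon_project_cpp(as.numeric(vol$values), as.integer(d),
                           vol$origin, vol$spacing, frame$source,
                           pix$x, pix$y, pix$z)
  structure(list(values = matrix(p, geom$detector_size[1], geom$detector_size[2]),
                 geometry = geom, noisy = FALSE),
            class = "drr_image")
}

#' @export
print.drr_image <- function(x, ...) {
  cat(sprintf("<drr_image> %d x %d px, range [%.4g, %.4g]%s\n",
              nrow(x$values), ncol(x$values), min(x$values), max(x$values),
              if (isTRUE(x$noisy)) ", noisy" else ""))
  invisible(x)
}

#' Quantum noise model for simulated projections
#'
#' Transmission noise as a combination of Poisson photon statistics and
#' additive Gaussian electronic noise: for a noise-free line integral `p_n`,
#' the detected intensity is
#' `I = Poisson(I0 exp(-p_n)) + Gaussian(0, sigma_e2)`.
#'
#' @param I0 incident photon intensity (default `1e5`).
#' @param sigma_e2 electronic noise variance (default 10).
#' @param seed optional integer seed applied by [add_noise()].
#' @return object of class `noise_model`.
#' @export
noise_model <- function(I0 = 1e5, sigma_e2 = 10, seed = NULL) {
  if (I0 <= 0) stop("I0 must be positive")
  if (sigma_e2 < 0) stop("sigma_e2 must be >= 0")
  structure(list(I0 = I0, sigma_e2 = sigma_e2, seed = seed),
            class = "noise_model")
}

#' Add quantum noise to a DRR
#'
#' Draws the noisy detected intensity per pixel under the [noise_model()]
#' law, clamps it to at least one photon (so the log stays defined), and
#' converts back to the line-integral domain, `-log(I / I0)`; the network
#' consumes projections in that domain.
#'
#' @param drr a [drr_image()] with noise-free line integrals.
#' @param noise a [noise_model()].
#' @return a [drr_image()] with `noisy = TRUE`.
#' @export
add_noise <- function(drr, noise) {
  if (!is.null(noise$seed)) set.seed(noise$seed)
  pn <- drr$values
  lambda <- noise$I0 * exp(-pn)
  if (any(lambda < 1))
    message(sprintf("add_noise: %d pixel(s) below one expected photon; clamped",
                    sum(lambda < 1)))
  I <- stats::rpois(length(lambda), lambda) +
    stats::rnorm(length(lambda), 0, sqrt(noise$sigma_e2))
  I[I < 1] <- 1
  out <- drr
  out$values <- matrix(-log(I / noise$I0), nrow(pn), ncol(pn))
  out$noisy <- TRUE
  out
}

#' First and second moments of an image
#'
#' @param mean,std mean and standard deviation of a DRR or measured
#'   projection intensity distribution (`std >= 0`).
#' @return object of class `intensity_stats`.
#' @export
intensity_stats <- function(mean, std) {
  if (std < 0) stop("std must be >= 0")
  structure(list(mean = mean, std = std), class = "intensity_stats")
}

#' @rdname intensity_stats
#' @param image a [drr_image()] or numeric matrix.
#' @export
intensity_stats_of <- function(image) {
  v <- if (inherits(image, "drr_image")) image$values else image
  intensity_stats(mean(v), stats::sd(as.numeric(v)))
}

#' Intensity correction between simulated DRRs and measured projections
#'
#' Reduces the intensity mismatch between simulated training DRRs and
#' measured CBCT projections. The default `"moment-match"` mode maps the DRR
#' to the projection's moments,
#' `(I - mean_DRR) / sigma_DRR * sigma_Proj + mean_Proj`, so the corrected
#' image has exactly the projection mean and standard deviation. The
#' `"as-printed"` mode applies the literal published correction
#' `(I - mean_Proj) * sigma_DRR / sigma_Proj + I` with the per-pixel value in
#' place of the DRR mean; it does not equalize moments and is kept for
#' comparison only.
#'
#' @param drr a [drr_image()] (or numeric matrix).
#' @param drr_stats,proj_stats [intensity_stats()] of the simulated DRR and
#'   of the measured projection (`proj_stats$std > 0`).
#' @param mode `"moment-match"` (default) or `"as-printed"`.
#' @return corrected image of the same class as the input.
#' @export
intensity_correct <- function(drr, drr_stats, proj_stats,
                              mode = c("moment-match", "as-printed")) {
  mode <- match.arg(mode)
  if (proj_stats$std <= 0) stop("projection std must be positive")
  v <- if (inherits(drr, "drr_image")) drr$values else drr
  if (mode == "moment-match") {
    if (drr_stats$std == 0) {
      warning("constant DRR; returning the projection mean everywhere")
      out <- matrix(proj_stats$mean, nrow(v), ncol(v))
    } else {
      out <- (v - drr_stats$mean) / drr_stats$std * proj_stats$std +
        proj_stats$mean
    }
  } else {
    out <- (v - proj_stats$mean) * drr_stats$std / proj_stats$std + v
  }
  if (inherits(drr, "drr_image")) { drr$values <- out; drr } else out
}

#' Write / read a DRR as 32-bit float TIFF with a JSON geometry sidecar
#'
#' @param drr a [drr_image()].
#' @param path output `.tif` path; the sidecar is written to
#'   `paste0(path, ".json")`.
#' @return `write_drr_tiff()` returns `path` invisibly; `read_drr_tiff()`
#'   the restored [drr_image()] (geometry restored from the sidecar when
#'   present).
#' @export
write_drr_tiff <- function(drr, path) {
  tiff::writeTIFF(drr$values, path, bits.per.sample = 32L,
                  reduce = FALSE)
  g <- drr$geometry
  side <- list(sad = g$sad, sdd = g$sdd, gantry_deg = g$gantry_deg,
               detector_size = g$detector_size, pixel_pitch = g$pixel_pitch,
               isocenter = g$isocenter, noisy = isTRUE(drr$noisy))
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_drr_tiff
#' @export
read_drr_tiff <- function(path) {
  v <- tiff::readTIFF(path, as.is = FALSE)
  side_path <- paste0(path, ".json")
  geom <- NULL; noisy <- FALSE
  if (file.exists(side_path)) {
    side <- jsonlite::read_json(side_path, simplifyVector = TRUE)
    geom <- cone_beam_geometry(side$sad, side$sdd, side$gantry_deg,
                               side$detector_size, side$pixel_pitch,
                               side$isocenter)
    noisy <- isTRUE(side$noisy)
  }
  structure(list(values = v, geometry = geom, noisy = noisy),
            class = "drr_image")
}
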