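#' Specification of the synthetic 4-D thorax phantom
#'
#' The phantom is an analytic scene of soft-edged ellipsoids (body, two
#' lungs, diaphragm, tumor) on a regular grid, deformed by a smooth
#' superior-inferior dominant displacement field. It stands in for a 4D-CT
#' acquisition: every phase volume comes with the exact deformation vector
#' field that maps the 0% reference phase onto it, so the downstream motion
#' model, projector and network can be validated against ground truth.
#'
#' Each ellipsoid is parameterized by centre (mm), semi-axes (mm) and linear
#' attenuation (mm^-1); structures are painted in order body, lungs,
#' diaphragm, tumor so the tumor keeps the highest attenuation. The peak
#' displacement `max_displacement` is reached at unit amplitude in the
#' inferior part of the thorax (diaphragm and tumor), decaying smoothly to
#' zero towards the lung apex; its anterior-posterior and left-right
#' components default to 30% and 10% of the superior-inferior component.
#'
#' @param grid_dims integer length-3, voxels per axis (each >= 16).
#' @param spacing mm per voxel.
#' @param max_displacement length-3 peak excursion (mm) in (x = LR,
#'   y = AP, z = SI) order.
#' @param body,lung_left,lung_right,diaphragm,tumor ellipsoid parameter lists
#'   with entries `center`, `semi_axes` (mm) and `attenuation` (mm^-1).
#' @param edge_mm soft-edge width of the ellipsoid boundaries (mm).
#' @param seed integer seed recorded with the spec (the phantom itself is
#'   deterministic; the seed feeds downstream samplers).
#' @return an object of class `phantom_spec`.
#' @export
phantom_spec <- function(grid_dims = c(64, 64, 64),
                         spacing = c(4, 4, 4),
                         max_displacement = c(1.2, 3.6, 12),
                         body = list(center = c(128, 128, 128),
                                     semi_axes = c(100, 80, 120),
                                     attenuation = 0.02),
                         lung_left = list(center = c(88, 128, 140),
                                          semi_axes = c(34, 40, 70),
                                          attenuation = 0.004),
                         lung_right = list(center = c(168, 128, 140),
                                           semi_axes = c(34, 40, 70),
                                           attenuation = 0.004),
                         diaphragm = list(center = c(128, 128, 36),
                                          semi_axes = c(90, 70, 44),
                                          attenuation = 0.022),
                         tumor = list(center = c(88, 128, 118),
                                      semi_axes = c(10, 10, 10),
                                      attenuation = 0.03),
                         edge_mm = 2,
                         seed = 1L) {
  spec <- structure(list(grid_dims = as.integer(grid_dims),
                         spacing = as.numeric(spacing),
                         max_displacement = as.numeric(max_displacement),
                         body = body, lung_left = lung_left,
                         lung_right = lung_right, diaphragm = diaphragm,
                         tumor = tumor, edge_mm = edge_mm,
                         seed = as.integer(seed)),
                    class = "phantom_spec")
  validate_phantom_spec(spec)
  spec
}

validate_phantom_spec <- function(spec) {
  if (any(spec$grid_dims < 16L)) stop("grid_dims must be >= 16 per axis")
  for (nm in c("body", "lung_left", "lung_right", "diaphragm", "tumor")) {
    e <- spec[[nm]]
    if (e$attenuation < 0) stop("attenuation values must be >= 0")
    if (any(e$semi_axes <= 0)) stop("semi-axes must be positive")
  }
  # Tumor strictly inside one lung: because every amplitude deforms the whole
  # scene with one smooth (injective at these magnitudes) map, containment at
  # the reference phase is preserved at every amplitude in [0, 1.15].
  tu <- spec$tumor
  inside <- vapply(list(spec$lung_left, spec$lung_right), function(lu) {
    # sample tumor surface points, check all strictly inside the lung
    th <- seq(0, pi, length.out = 9); ph <- seq(0, 2 * pi, length.out = 17)[-17]
    pts <- cbind(rep(sin(th), each = length(ph)) * cos(ph),
                 rep(sin(th), each = length(ph)) * sin(ph),
                 rep(cos(th), each = length(ph)))
    surf <- sweep(sweep(pts, 2, tu$semi_axes, "*"), 2, tu$center, "+")
    q <- sweep(sweep(surf, 2, lu$center, "-"), 2, lu$semi_axes, "/")
    all(rowSums(q^2) < 1)
  }, logical(1))
  if (!any(inside)) stop("tumor ellipsoid must lie strictly inside a lung")
  invisible(spec)
}

# Smooth SI weight: 1 in the inferior thorax (z <= z0), cosine ramp to 0 at
# the apex (z >= z1). C1-smooth; z in mm.
si_weight <- function(z, z0, z1) {
  w <- 0.5 * (1 + cos(pi * (z - z0) / (z1 - z0)))
  w[z <= z0] <- 1
  w[z >= z1] <- 0
  w
}

fov_mm <- function(spec) spec$grid_dims * spec$spacing

# Primary respiratory displacement mode, evaluated at world points
# (N x 3 mm). Returns N x 3 displacements (mm) at unit amplitude.
primary_mode <- function(spec, pts) {
  fov <- fov_mm(spec)
  z0 <- 0.60 * fov[3]; z1 <- 0.95 * fov[3]
  w <- si_weight(pts[, 3], z0, z1)
  cbind(spec$max_displacement[1] * w,
        spec$max_displacement[2] * w,
        spec$max_displacement[3] * w)
}

# Analytic attenuation of the reference-phase scene at world points.
scene_density <- function(spec, pts) {
  soft_mask <- function(e, pts) {
    q <- sweep(sweep(pts, 2, e$center, "-"), 2, e$semi_axes, "/")
    r <- sqrt(rowSums(q^2))
    # approximate signed distance (mm), positive inside
    d <- (1 - r) * min(e$semi_axes)
    m <- 0.5 + d / (2 * spec$edge_mm)
    m[m < 0] <- 0; m[m > 1] <- 1
    m
  }
  val <- numeric(nrow(pts))
  for (nm in c("body", "lung_left", "lung_right", "diaphragm", "tumor")) {
    e <- spec[[nm]]
    m <- soft_mask(e, pts)
    val <- val * (1 - m) + e$attenuation * m
  }
  val
}

# Voxelize the scene displaced by an arbitrary analytic displacement field
# `disp_fun(pts) -> N x 3` (pull-back: density evaluated at x + d(x)).
deform_phantom <- function(spec, disp_fun = NULL) {
  tmpl <- volume3d(array(0, dim = spec$grid_dims), spec$spacing, c(0, 0, 0))
  pts <- voxel_centers(tmpl)
  if (!is.null(disp_fun)) pts <- pts + disp_fun(pts)
  vals <- scene_density(spec, pts)
  volume3d(array(vals, dim = spec$grid_dims), spec$spacing, c(0, 0, 0))
}

check_amplitude <- function(amplitude) {
  if (!is.numeric(amplitude) || length(amplitude) != 1L ||
      !is.finite(amplitude) || amplitude < 0 || amplitude > 1.15)
    stop("amplitude must be a single value in [0, 1.15]")
  amplitude
}

#' Voxelize the phantom at a breathing amplitude
#'
#' Analytic voxelization of the displaced scene: the attenuation at voxel
#' centre `x` is the reference scene evaluated at `x + a * m(x)`, where `m`
#' is the phantom's primary displacement mode at unit amplitude. This makes
#' [make_phantom()] and [ground_truth_dvf()] exactly consistent under
#' pull-back warping. Deterministic for a fixed spec and amplitude.
#'
#' @param spec a [phantom_spec()].
#' @param amplitude breathing amplitude in `[0, 1.15]` (0 = reference phase).
#' @return a [volume3d()].
#' @export
make_phantom <- function(spec, amplitude = 0) {
  check_amplitude(amplitude)
  if (amplitude == 0) return(deform_phantom(spec, NULL))
  deform_phantom(spec, function(pts) amplitude * primary_mode(spec, pts))
}

#' Ground-truth deformation field at a breathing amplitude
#'
#' Returns the displacement field (pull-back convention, mm) that maps the
#' reference-phase phantom onto [make_phantom()] at the same amplitude:
#' `d(x) = a * m(x)` sampled at the voxel centres.
#'
#' @inheritParams make_phantom
#' @param phase optional phase tag stored on the result.
#' @return a [dvf_volume()].
#' @export
ground_truth_dvf <- function(spec, amplitude = 0, phase = NA_integer_) {
  check_amplitude(amplitude)
  tmpl <- volume3d(array(0, dim = spec$grid_dims), spec$spacing, c(0, 0, 0))
  pts <- voxel_centers(tmpl)
  d <- if (amplitude == 0) matrix(0, nrow(pts), 3) else
    amplitude * primary_mode(spec, pts)
  dvf_volume(array(d, dim = c(spec$grid_dims, 3L)), spec$spacing, c(0, 0, 0),
             phase = phase)
}

#' Periodic breathing trace
#'
#' Amplitude sequence `a_i = (1 - cos(2 pi i / n))^p / 2^p` over one cycle of
#' `n_phases` respiratory phases, so the reference phase 0 has amplitude 0
#' and peak inhale (amplitude `a_max`) occurs mid-cycle. The default `p = 1`
#' is the raised-cosine template.
#'
#' @param n_phases number of phase bins per cycle (>= 3, default 10).
#' @param a_max peak amplitude (default 1).
#' @param power exponent `p` shaping the template.
#' @return object of class `breathing_trace` with fields `amplitudes` (length
#'   `n_phases`, phase 0 first), `n_phases`, `model`.
#' @export
breathing_trace <- function(n_phases = 10L, a_max = 1, power = 1) {
  n_phases <- as.integer(n_phases)
  if (n_phases < 3L) stop("n_phases must be >= 3")
  i <- seq_len(n_phases) - 1L
  a <- a_max * ((1 - cos(2 * pi * i / n_phases)) / 2)^power
  a[1] <- 0
  structure(list(amplitudes = a, n_phases = n_phases, a_max = a_max,
                 model = sprintf("raised-cosine^%g", power)),
            class = "breathing_trace")
}

# Phase-dependence functions and relative displacement scales of the
# harmonic motion modes superimposed by generate_4dct(). Mode 1 is the
# primary (trace-amplitude) mode; modes 2..9 are smaller smooth fields with
# Fourier phase dependence, giving the 9 non-reference DVFs full rank with a
# variance spectrum dominated by the first three modes (~97% of the total),
# as observed for real respiratory DVF stacks.
harmonic_phase_functions <- function(n_phases) {
  th <- 2 * pi * (seq_len(n_phases) - 1L) / n_phases
  list(function(i) NA,  # placeholder; mode 1 uses the trace amplitude
       function(i) sin(th[i + 1L]),
       function(i) cos(2 * th[i + 1L]),
       function(i) sin(2 * th[i + 1L]),
       function(i) cos(3 * th[i + 1L]),
       function(i) sin(3 * th[i + 1L]),
       function(i) cos(4 * th[i + 1L]),
       function(i) sin(4 * th[i + 1L]),
       function(i) cos(5 * th[i + 1L]))
}

# Spatial patterns of modes 2..9 at world points; each returns N x 3 mm at
# unit mode amplitude, scaled relative to the SI peak displacement.
harmonic_modes <- function(spec) {
  fov <- fov_mm(spec)
  dz <- spec$max_displacement[3]
  # relative scales shaped like a typical DVF eigen-spectrum: the primary
  # mode dominates, modes 2-3 carry most of the remainder
  rel <- c(0.61, 1.0, 0.26, 0.25, 0.19, 0.15, 0.13, 0.11)
  bump <- function(pts, c_rel, s_rel) {
    q <- sweep(pts, 2, c_rel * fov, "-")
    exp(-rowSums(sweep(q, 2, s_rel * fov, "/")^2))
  }
  funs <- list(
    # mode 2: hysteresis - anterior-posterior shift lagging the SI motion
    function(pts) {
      w <- bump(pts, c(0.5, 0.5, 0.45), c(0.45, 0.40, 0.35))
      cbind(0.15 * w, w, 0.25 * w) * dz
    },
    # mode 3: lateral chest-wall expansion, antisymmetric in x
    function(pts) {
      w <- bump(pts, c(0.5, 0.5, 0.55), c(0.5, 0.45, 0.4))
      s <- (pts[, 1] - 0.5 * fov[1]) / (0.5 * fov[1])
      cbind(w * s, 0.2 * w, 0.1 * w * s) * dz
    },
    function(pts) { w <- bump(pts, c(0.35, 0.5, 0.5), c(0.25, 0.3, 0.3))
                    cbind(0.3 * w, 0.5 * w, w) * dz },
    function(pts) { w <- bump(pts, c(0.65, 0.45, 0.4), c(0.3, 0.25, 0.3))
                    cbind(w, 0.2 * w, 0.6 * w) * dz },
    function(pts) { w <- bump(pts, c(0.5, 0.65, 0.6), c(0.3, 0.25, 0.25))
                    cbind(0.2 * w, w, -0.5 * w) * dz },
    function(pts) { w <- bump(pts, c(0.45, 0.35, 0.35), c(0.25, 0.3, 0.25))
                    cbind(-0.6 * w, 0.4 * w, w) * dz },
    function(pts) { w <- bump(pts, c(0.6, 0.55, 0.7), c(0.25, 0.25, 0.2))
                    cbind(0.5 * w, -w, 0.5 * w) * dz },
    function(pts) { w <- bump(pts, c(0.35, 0.6, 0.25), c(0.2, 0.25, 0.25))
                    cbind(w, 0.5 * w, -0.7 * w) * dz })
  lapply(seq_along(funs), function(m) {
    f <- funs[[m]]; sc <- rel[m]
    function(pts) sc * f(pts)
  })
}

# Full multi-mode displacement field of phase i (0-based), pull-back mm.
phase_displacement_fun <- function(spec, trace, phase) {
  pf <- harmonic_phase_functions(trace$n_phases)
  hm <- harmonic_modes(spec)
  a <- trace$amplitudes[phase + 1L]
  coefs <- vapply(2:9, function(m) pf[[m]](phase) - pf[[m]](0),
                  numeric(1))
  function(pts) {
    d <- a * primary_mode(spec, pts)
    for (m in seq_along(hm)) {
      if (coefs[m] != 0) d <- d + coefs[m] * hm[[m]](pts)
    }
    d
  }
}

#' Generate a synthetic 4D-CT with ground-truth DVFs
#'
#' Produces one phantom volume and one deformation field per respiratory
#' phase. Phase 0 is the undeformed reference with an all-zero DVF. On top
#' of the primary amplitude mode, smaller smooth harmonic modes (hysteresis,
#' chest-wall expansion and localized residual motion, with Fourier phase
#' dependence) are superimposed so that the non-reference DVFs are linearly
#' independent and their PCA spectrum is dominated by the first three modes,
#' as for registration-derived 4D-CT fields. Volumes and DVFs are exactly
#' consistent: each phase volume is the analytic reference scene evaluated
#' at `x + d_i(x)`.
#'
#' @param spec a [phantom_spec()].
#' @param trace a [breathing_trace()].
#' @return list with `volumes` (list of [volume3d()]), `dvfs` (list of
#'   [dvf_volume()]), and `trace`.
#' @export
generate_4dct <- function(spec, trace = breathing_trace()) {
  if (trace$n_phases < 3L) stop("trace must have >= 3 phases")
  if (all(trace$amplitudes == 0))
    warning("degenerate breathing trace: all amplitudes are zero")
  tmpl <- volume3d(array(0, dim = spec$grid_dims), spec$spacing, c(0, 0, 0))
  pts <- voxel_centers(tmpl)
  volumes <- vector("list", trace$n_phases)
  dvfs <- vector("list", trace$n_phases)
  for (i in seq_len(trace$n_phases) - 1L) {
    if (i == 0L) {
      volumes[[1]] <- deform_phantom(spec, NULL)
      dvfs[[1]] <- dvf_volume(array(0, c(spec$grid_dims, 3L)), spec$spacing,
                              c(0, 0, 0), phase = 0L)
    } else {
      f <- phase_displacement_fun(spec, trace, i)
      d <- f(pts)
      vals <- scene_density(spec, pts + d)
      volumes[[i + 1L]] <- volume3d(array(vals, spec$grid_dims), spec$spacing,
                                    c(0, 0, 0))
      dvfs[[i + 1L]] <- dvf_volume(array(d, c(spec$grid_dims, 3L)),
                                   spec$spacing, c(0, 0, 0), phase = i)
    }
  }
  list(volumes = volumes, dvfs = dvfs, trace = trace)
}

#' Write a breathing trace as CSV
#'
#' @param trace a [breathing_trace()].
#' @param path output CSV path with columns `phase`, `amplitude`.
#' @export
write_trace_csv <- function(trace, path) {
  utils::write.csv(data.frame(phase = seq_along(trace$amplitudes) - 1L,
                              amplitude = trace$amplitudes),
                   path, row.names = FALSE)
  invisible(path)
}
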