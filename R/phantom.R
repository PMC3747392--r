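#' Generate a synthetic multi-tissue head phantom
#'
#' Builds a 3D head-like volume from nested ellipsoids so that every
#' downstream stage (interpolation, registration, evaluation) can be tested
#' without patient data. Tissue classes are written at fixed, documented
#' intensities: background 0, skull shell 220, cortical grey shell 180,
#' white-matter core 130, two off-centre ventricles 40, and one off-centre
#' bright lesion 240 that breaks rotational symmetry. A small seeded
#' Gaussian texture (SD 2) is added inside the head only, so the intensity
#' histogram keeps at least three well-separated modes.
#'
#' @param shape integer length-3 grid dimensions, each >= 8.
#' @param spacing voxel size in mm, default `c(1, 1, 1.3)` (anisotropic
#'   slice direction, as in typical 3D gradient-echo brain acquisitions).
#' @param seed integer random seed for the texture; the geometry is
#'   deterministic.
#' @param texture_sd within-tissue Gaussian texture SD in intensity units.
#' @return A [volume()] with intensities in `[0, 255]`.
#' @examples
#' ph <- generate_phantom(c(32, 32, 16), seed = 7)
#' range(ph$data)
#' @export
generate_phantom <- function(shape, spacing = c(1, 1, 1.3), seed = 1L,
                             texture_sd = 2) {
  shape <- as.integer(shape)
  if (length(shape) != 3 || any(is.na(shape)) || any(shape < 8))
    stop("`shape` must be 3 integers >= 8", call. = FALSE)
  spacing <- as.double(spacing)
  if (length(spacing) != 3 || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("`spacing` must be 3 positive numbers", call. = FALSE)

  # world-mm coordinates relative to the grid centre
  ax_coord <- function(n, sp) (seq_len(n) - 1 - (n - 1) / 2) * sp
  xs <- ax_coord(shape[1], spacing[1])
  ys <- ax_coord(shape[2], spacing[2])
  zs <- ax_coord(shape[3], spacing[3])
  # head semi-axes: 42% of the world extent per axis
  semi <- 0.42 * shape * spacing

  # normalized squared radius of every voxel w.r.t. an ellipsoid at
  # centre `c0` (fractions of the head semi-axes) with semi-axes `ax`
  r2 <- function(c0, ax) {
    dx2 <- ((xs - c0[1] * semi[1]) / (ax[1] * semi[1]))^2
    dy2 <- ((ys - c0[2] * semi[2]) / (ax[2] * semi[2]))^2
    dz2 <- ((zs - c0[3] * semi[3]) / (ax[3] * semi[3]))^2
    outer(outer(dx2, dy2, `+`), dz2, `+`)
  }

  head_r2 <- r2(c(0, 0, 0), c(1, 1, 1))
  img <- array(0, shape)
  img[head_r2 <= 1] <- 220                          # skull shell
  img[r2(c(0, 0, 0), c(0.88, 0.88, 0.88)) <= 1] <- 180   # grey shell
  img[r2(c(0, 0, 0), c(0.72, 0.72, 0.72)) <= 1] <- 130   # white core
  img[r2(c(0, 0.18, 0.05), c(0.14, 0.22, 0.25)) <= 1] <- 40   # ventricle 1
  img[r2(c(0, -0.18, 0.05), c(0.14, 0.22, 0.25)) <= 1] <- 40  # ventricle 2
  img[r2(c(0.3, 0.12, -0.2), c(0.1, 0.1, 0.1)) <= 1] <- 240   # lesion

  if (texture_sd > 0) {
    inside <- head_r2 <= 1
    tex <- with_seed(seed, stats::rnorm(sum(inside), sd = texture_sd))
    img[inside] <- img[inside] + tex
  }
  img <- pmin(pmax(img, 0), 255)
  volume(img, spacing = spacing)
}

#' Degradation protocol specification
#'
#' Describes the chain applied by [degrade()], in order: decimation along
#' one axis, rotation about the x-axis, translation, Gaussian blur along the
#' first in-plane axis, additive Gaussian noise. Defaults reproduce the
#' study conditions this package's experiments emulate: factor-2 slice
#' decimation, a 5-degree x-rotation, a (2, 3, 0) mm translation, noise
#' SD 10 and blur radius 5 voxels.
#'
#' @param subsample_axis `"x"`, `"y"`, or `"z"`.
#' @param subsample_factor positive integer decimation factor.
#' @param rotation_deg rotation about the x-axis in degrees.
#' @param translation_mm length-3 translation in mm.
#' @param noise_sd Gaussian noise SD in intensity units, >= 0.
#' @param blur_radius Gaussian blur radius in voxels, >= 0. The blur kernel
#'   uses `sigma = blur_radius / 2`, truncated at `+/- blur_radius` voxels.
#' @param seed integer seed for the noise realization.
#' @param blur_2d apply the blur along both in-plane axes instead of the
#'   first axis only (default `FALSE`: 1D horizontal blur).
#' @return A `degradation_spec` object.
#' @export
degradation_spec <- function(subsample_axis = "z", subsample_factor = 2L,
                             rotation_deg = 5, translation_mm = c(2, 3, 0),
                             noise_sd = 10, blur_radius = 5, seed = 1L,
                             blur_2d = FALSE) {
  subsample_axis <- match.arg(subsample_axis, c("x", "y", "z"))
  subsample_factor <- as.integer(subsample_factor)
  if (is.na(subsample_factor) || subsample_factor < 1L)
    stop("`subsample_factor` must be >= 1", call. = FALSE)
  if (noise_sd < 0 || blur_radius < 0)
    stop("`noise_sd` and `blur_radius` must be >= 0", call. = FALSE)
  translation_mm <- as.double(translation_mm)
  stopifnot(length(translation_mm) == 3, is.finite(rotation_deg))
  structure(list(subsample_axis = subsample_axis,
                 subsample_factor = subsample_factor,
                 rotation_deg = as.double(rotation_deg),
                 translation_mm = translation_mm,
                 noise_sd = as.double(noise_sd),
                 blur_radius = as.double(blur_radius),
                 seed = as.integer(seed),
                 blur_2d = isTRUE(blur_2d)),
            class = "degradation_spec")
}

#' Apply the degradation chain to a volume
#'
#' Applies, in order: pure decimation (every k-th slice, no anti-aliasing)
#' along the chosen axis with spacing multiplied accordingly; rotation about
#' the x-axis and translation, resampled trilinearly about the volume
#' centre; 1D (or in-plane 2D) Gaussian blur; additive Gaussian noise.
#' Deterministic for a fixed `spec$seed`.
#'
#' @param v a [volume()].
#' @param spec a [degradation_spec()].
#' @return The degraded [volume()].
#' @examples
#' ph <- generate_phantom(c(16, 16, 16), spacing = c(1, 1, 1.3), seed = 1)
#' lr <- degrade(ph, degradation_spec(noise_sd = 0, blur_radius = 0))
#' dim(lr$data)
#' @export
degrade <- function(v, spec) {
  stopifnot_volume(v)
  if (!inherits(spec, "degradation_spec"))
    stop("`spec` must be a degradation_spec", call. = FALSE)
  ai <- match(spec$subsample_axis, c("x", "y", "z"))
  k <- spec$subsample_factor
  d <- dim(v$data)
  if (k > d[ai])
    stop("subsample factor exceeds axis length", call. = FALSE)

  # 1. decimation: keep every k-th slice, length floor(L/k), spacing * k
  out <- v
  if (k > 1L) {
    keep <- seq_len(d[ai] %/% k) * k - (k - 1L)
    arr <- switch(ai,
                  v$data[keep, , , drop = FALSE],
                  v$data[, keep, , drop = FALSE],
                  v$data[, , keep, drop = FALSE])
    sp <- v$spacing; sp[ai] <- sp[ai] * k
    out <- volume(arr, spacing = sp, origin = v$origin)
  }

  # 2-3. rotation about x + translation, trilinear resampling onto the same
  # grid; the motion acts about the volume centre in world mm
  if (spec$rotation_deg != 0 || any(spec$translation_mm != 0)) {
    ctr <- volume_center_world(out)
    motion <- params_to_matrix(
      dof_params(translation = spec$translation_mm,
                 rotation = c(spec$rotation_deg, 0, 0), dof = 6),
      center = ctr)
    out <- resample_volume(out, dim(out$data), out$spacing,
                           world_map = motion,
                           spec = kernel_spec("trilinear"))
  }

  # 4. Gaussian blur, sigma = radius / 2, truncated at +/- radius voxels
  if (spec$blur_radius > 0) {
    axes <- if (spec$blur_2d) c(1L, 2L) else 1L
    arr <- out$data
    for (a in axes)
      arr <- blur_axis(arr, a, sigma = spec$blur_radius / 2,
                       radius = ceiling(spec$blur_radius))
    out <- volume(arr, spacing = out$spacing, origin = out$origin)
  }

  # 5. additive Gaussian noise, seeded
  if (spec$noise_sd > 0) {
    noise <- with_seed(spec$seed,
                       stats::rnorm(length(out$data), sd = spec$noise_sd))
    out <- volume(out$data + array(noise, dim(out$data)),
                  spacing = out$spacing, origin = out$origin)
  }
  out
}

# World-mm coordinate of the volume centre (midpoint of voxel centres).
volume_center_world <- function(v) {
  v$origin + (dim(v$data) - 1) / 2 * v$spacing
}

# 1D Gaussian blur along one array axis with edge replication.
blur_axis <- function(arr, axis, sigma, radius) {
  if (sigma <= 0 || radius < 1) return(arr)
  taps <- seq.int(-radius, radius)
  w <- exp(-taps^2 / (2 * sigma^2))
  w <- w / sum(w)
  n <- dim(arr)[axis]
  out <- array(0, dim(arr))
  base <- seq_len(n)
  for (j in seq_along(taps)) {
    idx <- pmin(pmax(base + taps[j], 1L), n)
    shifted <- switch(axis,
                      arr[idx, , , drop = FALSE],
                      arr[, idx, , drop = FALSE],
                      arr[, , idx, drop = FALSE])
    out <- out + w[j] * shifted
  }
  out
}

# Run expr with a temporary RNG state, restoring the caller's state.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}
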