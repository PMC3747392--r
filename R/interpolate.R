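#' Sample a volume at continuous voxel coordinates
#'
#' Evaluates the separable kernel-weighted sum
#' `sum I(X,Y,Z) k(x-X) k(y-Y) k(z-Z)` over the kernel footprint at each
#' requested point. Points are in continuous 0-based voxel coordinates
#' (voxel centres at integers). For interpolating kernels (all but the
#' B-splines, which are applied without prefiltering) grid values are
#' reproduced exactly at integer points.
#'
#' @param v a [volume()].
#' @param points n x 3 matrix (or length-3 vector) of continuous voxel
#'   coordinates.
#' @param spec a [kernel_spec()].
#' @return Numeric vector of sampled intensities, one per point.
#' @examples
#' v <- volume(array(1:27, c(3, 3, 3)))
#' sample_volume(v, c(1, 1, 1), kernel_spec("trilinear"))
#' @export
sample_volume <- function(v, points, spec = kernel_spec("trilinear")) {
  stopifnot_volume(v)
  if (is.null(dim(points))) points <- matrix(points, ncol = 3)
  points <- matrix(as.double(points), ncol = 3)
  if (any(!is.finite(points))) stop("points must be finite", call. = FALSE)
  .cpp_sample_points(as.vector(v$data), dim(v$data), points,
                     kernel_id(spec$name), spec$window_radius,
                     boundary_id(spec$boundary))
}

#' Resample a volume onto a new grid through a world-coordinate map
#'
#' Each output voxel centre is converted to world mm, mapped through
#' `world_map^-1` into the input volume's world frame, converted to input
#' continuous voxel coordinates, and sampled with the requested kernel.
#' `world_map` maps input world coordinates to output world coordinates;
#' the identity map therefore resamples in a shared world frame (the usual
#' case for upsampling and grid matching).
#'
#' @param v input [volume()].
#' @param out_shape integer length-3 output grid dimensions.
#' @param out_spacing output voxel spacing in mm.
#' @param world_map an [affine_transform()] from input world to output world
#'   coordinates (default identity).
#' @param spec a [kernel_spec()].
#' @param out_origin world mm of output voxel (0,0,0); defaults to the input
#'   origin.
#' @return A [volume()] on the requested grid. The attribute
#'   `"inside_fraction"` records the fraction of output voxels whose
#'   pull-back fell inside the input grid.
#' @export
resample_volume <- function(v, out_shape, out_spacing,
                            world_map = identity_transform(),
                            spec = kernel_spec("trilinear"),
                            out_origin = v$origin) {
  stopifnot_volume(v)
  out_shape <- as.integer(out_shape)
  if (length(out_shape) != 3 || any(out_shape < 2))
    stop("`out_shape` must be 3 integers >= 2", call. = FALSE)
  out_spacing <- as.double(out_spacing)
  if (length(out_spacing) != 3 || any(out_spacing <= 0))
    stop("`out_spacing` must be 3 positive numbers", call. = FALSE)
  minv <- unclass(solve(unclass(world_map)))
  res <- resample_core(v, out_shape, out_spacing, out_origin, minv, spec)
  out <- volume(array(res$values, out_shape), spacing = out_spacing,
                origin = as.double(out_origin))
  attr(out, "inside_fraction") <- mean(res$inside)
  out
}

# Core resampler: `inv_map` maps OUTPUT world -> INPUT world (4x4 plain
# matrix). Returns list(values, inside) on the output grid.
resample_core <- function(v, out_shape, out_spacing, out_origin, inv_map, spec) {
  # output voxel index -> output world: diag(out_spacing), offset out_origin
  # input world -> input voxel: diag(1/spacing), offset -origin/spacing
  o2w <- diag(4); diag(o2w)[1:3] <- out_spacing; o2w[1:3, 4] <- out_origin
  w2i <- diag(4); diag(w2i)[1:3] <- 1 / v$spacing
  w2i[1:3, 4] <- -v$origin / v$spacing
  M <- (w2i %*% inv_map %*% o2w)[1:3, , drop = FALSE]
  .cpp_resample_affine(as.vector(v$data), dim(v$data), M,
                       as.integer(out_shape), kernel_id(spec$name),
                       spec$window_radius, boundary_id(spec$boundary))
}

#' Resample to isotropic voxels
#'
#' Resamples a volume to cubic voxels at the minimum input spacing,
#' preserving the world extent to within one voxel (e.g. spacing
#' `(1, 1, 1.3)` with 120 z-slices becomes spacing `(1, 1, 1)` with 156
#' slices). Already-isotropic input is returned unchanged.
#'
#' @param v a [volume()].
#' @param spec a [kernel_spec()]; trilinear by default.
#' @return An isotropic [volume()].
#' @export
make_isotropic <- function(v, spec = kernel_spec("trilinear")) {
  stopifnot_volume(v)
  s <- min(v$spacing)
  if (all(v$spacing == s)) return(v)
  out_shape <- pmax(2L, as.integer(round(dim(v$data) * v$spacing / s)))
  resample_volume(v, out_shape, rep(s, 3), identity_transform(), spec)
}

#' Upsample or downsample along one axis by an integer factor
#'
#' Convenience wrapper over [resample_volume()] that changes the grid along
#' one axis while holding the world frame fixed, e.g. restoring a
#' slice-decimated volume to its original slice count.
#'
#' @param v a [volume()].
#' @param axis one of `"x"`, `"y"`, `"z"` (array dimensions 1, 2, 3).
#' @param out_len new axis length.
#' @param out_spacing_axis new spacing along that axis in mm.
#' @param spec a [kernel_spec()].
#' @return A [volume()].
#' @export
resample_axis <- function(v, axis = c("x", "y", "z"), out_len,
                          out_spacing_axis, spec = kernel_spec("trilinear")) {
  axis <- match.arg(axis)
  ai <- match(axis, c("x", "y", "z"))
  shape <- dim(v$data); shape[ai] <- as.integer(out_len)
  sp <- v$spacing; sp[ai] <- out_spacing_axis
  resample_volume(v, shape, sp, identity_transform(), spec)
}
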