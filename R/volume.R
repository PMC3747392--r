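#' Construct a 3D volume
#'
#' A `volume` is the package's universal container: a 3D array of scalar
#' intensities together with per-axis voxel spacing (mm) and the world
#' coordinate (mm) of the centre of voxel `(0,0,0)`. Voxel indices are
#' 0-based in all coordinate arithmetic; a voxel centre at index `i` sits at
#' world position `origin + i * spacing` along each axis.
#'
#' @param data 3D numeric array of finite intensities; each axis length >= 2.
#' @param spacing numeric length-3, strictly positive voxel sizes in mm.
#' @param origin numeric length-3, world position (mm) of voxel (0,0,0).
#' @return An object of class `volume` with elements `data`, `spacing`,
#'   `origin`.
#' @examples
#' v <- volume(array(rnorm(8 * 8 * 8), c(8, 8, 8)), spacing = c(1, 1, 1.3))
#' dim(v$data)
#' @export
volume <- function(data, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("`data` must be a 3D array", call. = FALSE)
  if (any(dim(data) < 2L))
    stop("each axis must have length >= 2", call. = FALSE)
  data <- array(as.double(data), dim(data))
  if (!all(is.finite(data)))
    stop("all intensities must be finite", call. = FALSE)
  spacing <- as.double(spacing)
  origin <- as.double(origin)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("`spacing` must be 3 strictly positive numbers", call. = FALSE)
  if (length(origin) != 3L || any(!is.finite(origin)))
    stop("`origin` must be 3 finite numbers", call. = FALSE)
  structure(list(data = data, spacing = spacing, origin = origin),
            class = "volume")
}

#' @export
print.volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<volume> %d x %d x %d, spacing %s mm, origin (%s) mm\n",
              d[1], d[2], d[3],
              paste(format(x$spacing, digits = 4), collapse = " x "),
              paste(format(x$origin, digits = 4), collapse = ", ")))
  cat(sprintf("  intensity range [%.4g, %.4g]\n",
              min(x$data), max(x$data)))
  invisible(x)
}

#' @rdname volume
#' @param x object to test.
#' @export
is_volume <- function(x) inherits(x, "volume")

stopifnot_volume <- function(v, arg = "v") {
  if (!is_volume(v)) stop(sprintf("`%s` must be a volume", arg), call. = FALSE)
  invisible(v)
}

stopifnot_same_grid <- function(a, b) {
  if (!identical(dim(a$data), dim(b$data)))
    stop("volumes must share the same grid dimensions", call. = FALSE)
  invisible(NULL)
}

#' World coordinates of voxel centres
#'
#' @param v a [volume()].
#' @param idx integer matrix (n x 3) of 0-based voxel indices.
#' @return n x 3 matrix of world coordinates in mm.
#' @keywords internal
voxel_to_world <- function(v, idx) {
  idx <- matrix(as.double(idx), ncol = 3)
  sweep(sweep(idx, 2, v$spacing, `*`), 2, v$origin, `+`)
}

#' Read and write volumes as NIfTI-1
#'
#' `write_volume()` stores the array with its spacing in the NIfTI `pixdim`
#' and the origin in the sform translation; `read_volume()` recovers them.
#' A plain-text fallback (`write_volume_raw()` / `read_volume_raw()`) stores
#' the voxel data as a raw float32 stream beside a JSON sidecar describing
#' shape, spacing and origin.
#'
#' @param v a [volume()].
#' @param path file path (`.nii` or `.nii.gz` for the NIfTI pair;
#'   for the raw pair, `path` is the data file and `<path>.json` the sidecar).
#' @return `read_volume()` and `read_volume_raw()` return a [volume()];
#'   the writers return `path` invisibly.
#' @export
write_volume <- function(v, path) {
  stopifnot_volume(v)
  img <- RNifti::asNifti(v$data)
  RNifti::pixdim(img) <- v$spacing
  # sform: diagonal spacing with the origin as translation
  xform <- diag(c(v$spacing, 1))
  xform[1:3, 4] <- v$origin
  RNifti::sform(img) <- structure(xform, code = 2L)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_volume
#' @export
read_volume <- function(path) {
  img <- RNifti::readNifti(path)
  arr <- array(as.double(img), dim(img)[1:3])
  sp <- RNifti::pixdim(img)[1:3]
  xf <- try(RNifti::xform(img), silent = TRUE)
  org <- if (!inherits(xf, "try-error") && is.matrix(xf)) xf[1:3, 4] else c(0, 0, 0)
  volume(arr, spacing = abs(sp), origin = as.double(org))
}

#' @rdname write_volume
#' @export
write_volume_raw <- function(v, path) {
  stopifnot_volume(v)
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.vector(v$data), con, size = 4)
  meta <- list(shape = dim(v$data), spacing = v$spacing, origin = v$origin,
               dtype = "float32", order = "column-major")
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = FALSE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_volume
#' @export
read_volume_raw <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  n <- prod(meta$shape)
  con <- file(path, "rb")
  on.exit(close(con))
  dat <- readBin(con, what = "double", n = n, size = 4)
  volume(array(dat, meta$shape), spacing = meta$spacing, origin = meta$origin)
}
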