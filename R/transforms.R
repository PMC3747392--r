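#' Homogeneous affine transforms
#'
#' Affine transforms are represented as 4x4 homogeneous matrices acting on
#' world coordinates in mm, with bottom row `(0, 0, 0, 1)`. Constructors are
#' provided for the elementary translation, scaling, rotation and shear
#' transforms; arbitrary transforms are composed by matrix multiplication
#' (`%*%`).
#'
#' @param m a 4x4 numeric matrix.
#' @return An `affine_transform` object (a classed 4x4 matrix).
#' @export
affine_transform <- function(m) {
  m <- as.matrix(m)
  if (!identical(dim(m), c(4L, 4L)) || any(!is.finite(m)))
    stop("`m` must be a finite 4x4 matrix", call. = FALSE)
  if (!isTRUE(all.equal(m[4, ], c(0, 0, 0, 1), tolerance = 1e-12)))
    stop("bottom row must be (0, 0, 0, 1)", call. = FALSE)
  m[4, ] <- c(0, 0, 0, 1)
  structure(m, class = c("affine_transform", "matrix", "array"))
}

#' @rdname affine_transform
#' @export
identity_transform <- function() affine_transform(diag(4))

#' @export
print.affine_transform <- function(x, ...) {
  cat("<affine_transform>\n")
  print(unclass(x))
  invisible(x)
}

#' Apply an affine transform to points
#'
#' @param tf an [affine_transform()].
#' @param pts n x 3 matrix (or length-3 vector) of world coordinates in mm.
#' @return n x 3 matrix of transformed coordinates.
#' @export
apply_transform <- function(tf, pts) {
  if (is.null(dim(pts))) pts <- matrix(pts, ncol = 3)
  h <- cbind(pts, 1) %*% t(unclass(tf))
  h[, 1:3, drop = FALSE]
}

compose <- function(...) {
  ms <- list(...)
  out <- Reduce(`%*%`, lapply(ms, unclass))
  affine_transform(out)
}

#' Elementary affine transforms
#'
#' `translation_matrix()` adds the vector `t`; `scaling_matrix()` scales each
#' axis; `rotation_matrix()` is a proper rotation about one coordinate axis
#' through the origin (angle in degrees); `shear_matrix()` is unit-diagonal
#' upper-triangular with entries `(hxy, hxz, hyz)`.
#'
#' @param t length-3 translation in mm.
#' @return An [affine_transform()].
#' @examples
#' apply_transform(translation_matrix(c(2, 3, 0)), c(0, 0, 0))
#' apply_transform(rotation_matrix("z", 90), c(1, 0, 0))
#' @export
translation_matrix <- function(t) {
  t <- as.double(t)
  if (length(t) != 3 || any(!is.finite(t)))
    stop("`t` must be 3 finite numbers", call. = FALSE)
  m <- diag(4)
  m[1:3, 4] <- t
  affine_transform(m)
}

#' @rdname translation_matrix
#' @param s length-3 positive scale factors (a scalar is recycled).
#' @export
scaling_matrix <- function(s) {
  s <- as.double(s)
  if (length(s) == 1) s <- rep(s, 3)
  if (length(s) != 3 || any(!is.finite(s)) || any(s <= 0))
    stop("`s` must be 3 strictly positive numbers", call. = FALSE)
  affine_transform(diag(c(s, 1)))
}

#' @rdname translation_matrix
#' @param axis one of `"x"`, `"y"`, `"z"`.
#' @param theta rotation angle in degrees.
#' @export
rotation_matrix <- function(axis = c("x", "y", "z"), theta) {
  axis <- match.arg(axis)
  if (!is.finite(theta)) stop("`theta` must be finite", call. = FALSE)
  a <- theta * pi / 180
  c_ <- cos(a); s_ <- sin(a)
  r <- switch(axis,
              x = rbind(c(1, 0, 0), c(0, c_, -s_), c(0, s_, c_)),
              y = rbind(c(c_, 0, s_), c(0, 1, 0), c(-s_, 0, c_)),
              z = rbind(c(c_, -s_, 0), c(s_, c_, 0), c(0, 0, 1)))
  m <- diag(4)
  m[1:3, 1:3] <- r
  affine_transform(m)
}

#' @rdname translation_matrix
#' @param h length-3 shear coefficients `(hxy, hxz, hyz)` (dimensionless).
#' @export
shear_matrix <- function(h) {
  h <- as.double(h)
  if (length(h) != 3 || any(!is.finite(h)))
    stop("`h` must be 3 finite numbers", call. = FALSE)
  m <- diag(4)
  m[1, 2] <- h[1]; m[1, 3] <- h[2]; m[2, 3] <- h[3]
  affine_transform(m)
}

#' Degrees-of-freedom parameter vector
#'
#' Bundles the affine parameters used by the registration search. The `dof`
#' field declares how many are free: 3 (translation), 4 (+ global scale),
#' 6 (rigid), 7 (rigid + global scale), 9 (+ per-axis scales),
#' 12 (+ shears). Fields beyond the declared `dof` must sit at their neutral
#' values (zero translation/rotation/shear, unit scale).
#'
#' @param translation length-3, mm.
#' @param rotation length-3 Euler angles in degrees, applied as `Rz Ry Rx`.
#' @param scale length-3 positive scales (scalar recycled).
#' @param shear length-3 shear coefficients.
#' @param dof one of 3, 4, 6, 7, 9, 12.
#' @return A `dof_params` object.
#' @export
dof_params <- function(translation = c(0, 0, 0), rotation = c(0, 0, 0),
                       scale = c(1, 1, 1), shear = c(0, 0, 0), dof = 12) {
  translation <- as.double(translation)
  rotation <- as.double(rotation)
  scale <- as.double(scale)
  if (length(scale) == 1) scale <- rep(scale, 3)
  shear <- as.double(shear)
  dof <- as.integer(dof)
  if (!dof %in% c(3L, 4L, 6L, 7L, 9L, 12L))
    stop("`dof` must be one of 3, 4, 6, 7, 9, 12", call. = FALSE)
  stopifnot(length(translation) == 3, length(rotation) == 3,
            length(scale) == 3, length(shear) == 3)
  if (any(scale <= 0)) stop("scales must be > 0", call. = FALSE)
  if (dof < 6 && any(rotation != 0))
    stop("rotations must be neutral below 6 DOF", call. = FALSE)
  if (dof %in% c(3L, 6L) && any(scale != 1))
    stop("scales must be neutral at 3 or 6 DOF", call. = FALSE)
  if (dof %in% c(4L, 7L) && length(unique(scale)) != 1)
    stop("scale must be global (equal per axis) at 4 or 7 DOF", call. = FALSE)
  if (dof < 12 && any(shear != 0))
    stop("shears must be neutral below 12 DOF", call. = FALSE)
  structure(list(translation = translation, rotation = rotation,
                 scale = scale, shear = shear, dof = dof),
            class = "dof_params")
}

#' @export
print.dof_params <- function(x, ...) {
  cat(sprintf(
    "<dof_params> %d DOF: t = (%s) mm, r = (%s) deg, s = (%s), h = (%s)\n",
    x$dof,
    paste(format(x$translation, digits = 4), collapse = ", "),
    paste(format(x$rotation, digits = 4), collapse = ", "),
    paste(format(x$scale, digits = 4), collapse = ", "),
    paste(format(x$shear, digits = 4), collapse = ", ")))
  invisible(x)
}

#' Build the affine matrix for a parameter vector
#'
#' Uses the fixed composition
#' `T(translation) . C . Rz Ry Rx . S . H . C^-1`, where `C` recentres the
#' rotation/scale/shear about `center` (typically the volume centre in world
#' mm). Neutral parameters give the identity.
#'
#' @param p a [dof_params()].
#' @param center length-3 world point (mm) about which rotation, scaling and
#'   shear act.
#' @return An [affine_transform()].
#' @export
params_to_matrix <- function(p, center = c(0, 0, 0)) {
  if (!inherits(p, "dof_params")) stop("`p` must be dof_params", call. = FALSE)
  center <- as.double(center)
  rot <- compose(rotation_matrix("z", p$rotation[3]),
                 rotation_matrix("y", p$rotation[2]),
                 rotation_matrix("x", p$rotation[1]))
  compose(translation_matrix(p$translation),
          translation_matrix(center),
          rot,
          scaling_matrix(p$scale),
          shear_matrix(p$shear),
          translation_matrix(-center))
}

#' Recover parameters from an affine matrix
#'
#' Inverse of [params_to_matrix()] for the same composition and centre:
#' decomposes the 3x3 block as `Rz Ry Rx . S . H` (QR-style) and extracts
#' translation, Euler angles (degrees), scales and shears. Valid away from
#' gimbal lock (`|ry| = 90` degrees).
#'
#' @param tf an [affine_transform()].
#' @param center the centre used when the matrix was built.
#' @return A [dof_params()] with `dof = 12`.
#' @export
matrix_to_params <- function(tf, center = c(0, 0, 0)) {
  m <- unclass(tf)
  A <- m[1:3, 1:3]
  # Euler angles from R = Rz Ry Rx applied to A = R S H (S H upper triangular
  # with positive diagonal): use a Gram-Schmidt/QR of A's columns.
  qr_ <- qr(A)
  R <- qr.Q(qr_)
  U <- qr.R(qr_)
  # enforce positive diagonal on U
  sgn <- sign(diag(U)); sgn[sgn == 0] <- 1
  R <- R %*% diag(sgn)
  U <- diag(sgn) %*% U
  if (det(R) < 0) { R <- -R; U <- -U }  # proper rotation
  ry <- asin(pmin(pmax(-R[3, 1], -1), 1))
  if (abs(cos(ry)) < 1e-9)
    stop("gimbal lock: cannot recover Euler angles", call. = FALSE)
  rx <- atan2(R[3, 2], R[3, 3])
  rz <- atan2(R[2, 1], R[1, 1])
  s <- diag(U)
  # S H is upper triangular with rows scaled by the row's scale factor
  h <- c(U[1, 2] / s[1], U[1, 3] / s[1], U[2, 3] / s[2])
  # translation: T = M - C R S H C^-1 contribution
  rsh <- R %*% U
  t_ <- m[1:3, 4] - (center - rsh %*% center)
  dof_params(translation = as.double(t_),
             rotation = c(rx, ry, rz) * 180 / pi,
             scale = s, shear = h, dof = 12)
}

#' Read and write transforms as plain text
#'
#' The file format is four whitespace-separated rows of four numbers (world
#' mm convention). `write_transform_json()` additionally stores a DOF
#' parameter vector as JSON.
#'
#' @param tf an [affine_transform()].
#' @param path file path.
#' @return Readers return the stored object; writers return `path` invisibly.
#' @export
write_transform <- function(tf, path) {
  m <- unclass(tf)
  lines <- apply(m, 1, function(r) paste(sprintf("%.12g", r), collapse = " "))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_transform
#' @export
read_transform <- function(path) {
  m <- as.matrix(utils::read.table(path, header = FALSE))
  dimnames(m) <- NULL
  affine_transform(m)
}

#' @rdname write_transform
#' @param p a [dof_params()].
#' @export
write_transform_json <- function(p, path) {
  jsonlite::write_json(unclass(p), path, auto_unbox = FALSE, digits = NA)
  invisible(path)
}

#' @rdname write_transform
#' @export
read_transform_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  dof_params(x$translation, x$rotation, x$scale, x$shear, x$dof)
}
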