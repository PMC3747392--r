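#' Interpolation kernel specification
#'
#' Describes one of the eight separable interpolation kernels used throughout
#' the package. The support radius is fixed by the kernel family (nearest
#' 0.5, trilinear 1, cubic/quintic/heptic Lagrange 2/3/4, cubic B-spline 2,
#' quartic B-spline 2.5) except for the windowed sinc, whose radius equals
#' `window_radius`.
#'
#' @param name one of `"nearest"`, `"trilinear"`, `"lagrange4"`,
#'   `"lagrange6"`, `"lagrange8"`, `"bspline3"`, `"bspline4"`,
#'   `"windowed_sinc"`.
#' @param boundary out-of-grid policy: `"clamp"` (replicate edge, default),
#'   `"zero"`, or `"mirror"`.
#' @param window_radius windowed sinc only: half-width of the Hann-windowed
#'   sinc in voxels (integer >= 1, default 4).
#' @return A `kernel_spec` object with elements `name`, `support_radius`,
#'   `boundary`, `window_radius`.
#' @examples
#' kernel_spec("trilinear")
#' kernel_spec("windowed_sinc", window_radius = 3)
#' @export
kernel_spec <- function(name = c("trilinear", "nearest", "lagrange4",
                                 "lagrange6", "lagrange8", "bspline3",
                                 "bspline4", "windowed_sinc"),
                        boundary = c("clamp", "zero", "mirror"),
                        window_radius = 4L) {
  name <- match.arg(name)
  boundary <- match.arg(boundary)
  window_radius <- as.integer(window_radius)
  if (name == "windowed_sinc" && (is.na(window_radius) || window_radius < 1L))
    stop("`window_radius` must be an integer >= 1", call. = FALSE)
  support <- switch(name,
                    nearest = 0.5, trilinear = 1, lagrange4 = 2,
                    lagrange6 = 3, lagrange8 = 4, bspline3 = 2,
                    bspline4 = 2.5, windowed_sinc = as.double(window_radius))
  structure(list(name = name, support_radius = support, boundary = boundary,
                 window_radius = window_radius),
            class = "kernel_spec")
}

#' @export
print.kernel_spec <- function(x, ...) {
  cat(sprintf("<kernel_spec> %s (support %.1f voxels, boundary %s)\n",
              x$name, x$support_radius, x$boundary))
  invisible(x)
}

#' All kernel names
#'
#' @return Character vector of the eight kernel names in the order used by
#'   the experiment tables.
#' @export
kernel_names <- function() {
  c("trilinear", "nearest", "bspline3", "bspline4",
    "lagrange4", "lagrange6", "lagrange8", "windowed_sinc")
}

kernel_id <- function(name) {
  match(name, c("nearest", "trilinear", "lagrange4", "lagrange6",
                "lagrange8", "bspline3", "bspline4", "windowed_sinc")) - 1L
}

boundary_id <- function(boundary) {
  match(boundary, c("zero", "clamp", "mirror")) - 1L
}

#' Central Lagrange interpolation kernel
#'
#' Evaluates the 1D piecewise-polynomial kernel obtained by passing a
#' polynomial of degree `N - 1` through `N` equidistant supporting points.
#' `N = 1` is the nearest-neighbour box kernel and `N = 2` the linear (hat)
#' kernel; `N = 4`, `6`, `8` give the cubic, quintic and heptic kernels.
#' Weights are generated from the Lagrange product formula, not from
#' transcribed per-branch polynomials.
#'
#' @param N number of supporting points, one of 1, 2, 4, 6, 8.
#' @param x signed voxel offset(s), finite.
#' @return Kernel weight(s), zero for `|x| >= N/2` (`|x| >= 0.5` for `N = 1`).
#' @examples
#' lagrange_kernel(4, 0)     # 1: interpolation condition
#' lagrange_kernel(4, 0.5)   # 0.5625
#' lagrange_kernel(2, 0.3)   # 0.7: the hat kernel
#' @export
lagrange_kernel <- function(N, x) {
  if (!N %in% c(1, 2, 4, 6, 8))
    stop("`N` must be one of 1, 2, 4, 6, 8", call. = FALSE)
  if (any(!is.finite(x))) stop("`x` must be finite", call. = FALSE)
  if (N == 1) return(as.double(x >= -0.5 & x < 0.5))
  half <- N / 2
  vapply(as.double(x), function(xi) {
    if (abs(xi) >= half) return(0)
    # decompose offset: xi = f - k with f in [0,1), k the relative tap index
    k <- -floor(xi)
    f <- xi + k
    m <- setdiff(seq.int(-(half - 1), half), k)
    prod((f - m) / (k - m))
  }, numeric(1))
}

#' Cox-de Boor B-spline basis function
#'
#' Evaluates the order-`k` B-spline basis `N[i,k](t)` on an arbitrary
#' non-decreasing knot vector via the two-term recursion, with the usual
#' `0/0 := 0` convention. The curve `P(t) = sum_i N[i,k](t) P_i` is valid on
#' `[t_k, t_{n+2})` for `n + 1` control points.
#'
#' @param i basis index (1-based into the knot vector).
#' @param k spline order (degree `k - 1`), integer >= 1.
#' @param t evaluation parameter (scalar).
#' @param knots non-decreasing numeric knot vector.
#' @param check when `TRUE` (default), error if `t` lies outside the valid
#'   range `[t_k, t_{n+2})` implied by the knot vector.
#' @return The non-negative basis weight.
#' @examples
#' kn <- open_uniform_knots(k = 4, n_control = 7)
#' sum(vapply(1:7, bspline_basis, numeric(1), k = 4, t = 2.5, knots = kn))
#' @export
bspline_basis <- function(i, k, t, knots, check = TRUE) {
  knots <- as.double(knots)
  if (is.unsorted(knots)) stop("`knots` must be non-decreasing", call. = FALSE)
  n_basis <- length(knots) - k      # number of basis functions = n + 1
  if (check) {
    lo <- knots[k]
    hi <- knots[n_basis + 1]        # t_{n+2}
    if (t < lo || t >= hi)
      stop(sprintf("`t` = %g outside the valid range [%g, %g)", t, lo, hi),
           call. = FALSE)
  }
  cox_de_boor(i, k, t, knots)
}

cox_de_boor <- function(i, k, t, knots) {
  if (k == 1) {
    return(as.double(t >= knots[i] && t < knots[i + 1]))
  }
  d1 <- knots[i + k - 1] - knots[i]
  d2 <- knots[i + k] - knots[i + 1]
  a <- if (d1 > 0) (t - knots[i]) / d1 * cox_de_boor(i, k - 1, t, knots) else 0
  b <- if (d2 > 0) (knots[i + k] - t) / d2 * cox_de_boor(i + 1, k - 1, t, knots) else 0
  a + b
}

#' Open-uniform knot vector
#'
#' Builds a knot vector with `k` equal knots at each end and uniformly spaced
#' interior knots, e.g. `(0,0,0,1,2,3,4,4,4)` for `k = 3`, `n_control = 6`.
#'
#' @param k spline order.
#' @param n_control number of control points (`n + 1`); must exceed `k - 1`.
#' @return Numeric knot vector of length `k + n_control`.
#' @export
open_uniform_knots <- function(k, n_control) {
  k <- as.integer(k); n_control <- as.integer(n_control)
  if (k < 2) stop("`k` must be >= 2", call. = FALSE)
  if (n_control < k) stop("need at least `k` control points", call. = FALSE)
  n_int <- n_control - k + 1        # interior spans
  c(rep(0, k), seq_len(n_int - 1), rep(n_int, k))
}

#' Centred cardinal B-spline kernel
#'
#' The symmetric degree-`d` B-spline kernel (uniform integer knots centred on
#' zero) used for direct-convolution B-spline sampling. No prefiltering is
#' applied by default during resampling, so this kernel smooths rather than
#' interpolates (`bspline_kernel(3, 0) == 2/3`, not 1).
#'
#' @param degree spline degree: 3 (cubic) or 4 (quartic).
#' @param x signed voxel offset(s).
#' @return Kernel weight(s); support is `(-(degree+1)/2, (degree+1)/2)`.
#' @export
bspline_kernel <- function(degree, x) {
  if (!degree %in% c(3, 4)) stop("`degree` must be 3 or 4", call. = FALSE)
  vapply(as.double(x), function(xi) bspline_card_r(degree, xi), numeric(1))
}

bspline_card_r <- function(degree, x) {
  if (degree == 0) return(as.double(x >= -0.5 & x < 0.5))
  h <- (degree + 1) / 2
  ((x + h) * bspline_card_r(degree - 1, x + 0.5) +
     (h - x) * bspline_card_r(degree - 1, x - 0.5)) / degree
}

#' Hann-windowed sinc kernel
#'
#' `sinc(pi x)` multiplied by a Hann window of the given half-width:
#' `0.5 (1 + cos(pi x / radius))` for `|x| < radius`, zero outside. The
#' kernel equals 1 at `x = 0` and 0 at all other integers, so it
#' interpolates; for low-frequency band-limited signals it approaches exact
#' reconstruction as the radius grows.
#'
#' @param x signed voxel offset(s).
#' @param radius window half-width in voxels (integer >= 1).
#' @return Kernel weight(s).
#' @examples
#' windowed_sinc_kernel(0, 3)   # 1
#' windowed_sinc_kernel(1, 3)   # 0
#' @export
windowed_sinc_kernel <- function(x, radius) {
  radius <- as.integer(radius)
  if (is.na(radius) || radius < 1) stop("`radius` must be >= 1", call. = FALSE)
  vapply(as.double(x), function(xi) {
    if (abs(xi) >= radius) return(0)
    s <- if (xi == 0) 1 else sin(pi * xi) / (pi * xi)
    s * 0.5 * (1 + cos(pi * xi / radius))
  }, numeric(1))
}

#' Evaluate any named kernel at signed offsets
#'
#' Dispatches to the kernel family named in `spec`; used by validation code
#' and by the separable resampler's unit tests.
#'
#' @param spec a [kernel_spec()].
#' @param x signed voxel offset(s).
#' @return Kernel weight(s).
#' @export
kernel_weight <- function(spec, x) {
  switch(spec$name,
         nearest = lagrange_kernel(1, x),
         trilinear = lagrange_kernel(2, x),
         lagrange4 = lagrange_kernel(4, x),
         lagrange6 = lagrange_kernel(6, x),
         lagrange8 = lagrange_kernel(8, x),
         bspline3 = bspline_kernel(3, x),
         bspline4 = bspline_kernel(4, x),
         windowed_sinc = windowed_sinc_kernel(x, spec$window_radius))
}
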