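#' Similarity cost specification
#'
#' Names one of the four intensity cost functions used during registration.
#' All four are exposed as minimized costs (0 at perfect alignment for LS,
#' NCC and NMI-cost; the correlation-ratio cost is `1 - eta^2`).
#'
#' @param name `"LS"` (least squares), `"CR"` (correlation ratio),
#'   `"NCC"` (normalized cross-correlation), or `"NMI"` (normalized mutual
#'   information).
#' @param bins histogram bin count used by CR and NMI (>= 2, default 64).
#' @return A `cost_spec` object.
#' @export
cost_spec <- function(name = c("LS", "CR", "NCC", "NMI"), bins = 64L) {
  name <- match.arg(toupper(name), c("LS", "CR", "NCC", "NMI"))
  bins <- as.integer(bins)
  if (is.na(bins) || bins < 2L) stop("`bins` must be >= 2", call. = FALSE)
  structure(list(name = name, bins = bins), class = "cost_spec")
}

#' @export
print.cost_spec <- function(x, ...) {
  cat(sprintf("<cost_spec> %s (bins %d)\n", x$name, x$bins))
  invisible(x)
}

#' Cost function names
#' @return The four cost names in table order.
#' @export
cost_names <- function() c("CR", "LS", "NCC", "NMI")

#' Least-squares cost
#'
#' Mean squared intensity difference `sum((R - I)^2) / N` over the voxels of
#' two volumes on the same grid.
#'
#' @param R,I [volume()]s on identical grids.
#' @return Non-negative scalar cost.
#' @export
least_squares <- function(R, I) {
  stopifnot_volume(R, "R"); stopifnot_volume(I, "I")
  stopifnot_same_grid(R, I)
  mean((R$data - I$data)^2)
}

#' Joint intensity histogram
#'
#' Bins the paired intensities of two same-grid volumes into a `bins x bins`
#' co-occurrence table. Each image's intensity range is linearly rescaled to
#' `[0, bins)` before binning, so the histogram depends only on relative
#' intensities.
#'
#' @param R,I [volume()]s on identical grids.
#' @param bins number of bins per image (>= 2).
#' @param on_degenerate what to do when an image has zero intensity range:
#'   `"error"` (default) or `"single-bin"` (place all its mass in bin 1).
#' @return A `joint_histogram`: list with `counts` (bins x bins integer
#'   matrix), `edges_a`, `edges_b` (bin boundaries in original intensity
#'   units) and `n_voxels`.
#' @export
joint_histogram <- function(R, I, bins = 64L,
                            on_degenerate = c("error", "single-bin")) {
  stopifnot_volume(R, "R"); stopifnot_volume(I, "I")
  stopifnot_same_grid(R, I)
  on_degenerate <- match.arg(on_degenerate)
  bins <- as.integer(bins)
  if (is.na(bins) || bins < 2L) stop("`bins` must be >= 2", call. = FALSE)
  ja <- bin_indices(as.vector(R$data), bins, on_degenerate)
  jb <- bin_indices(as.vector(I$data), bins, on_degenerate)
  counts <- matrix(tabulate((ja$bin - 1L) * bins + jb$bin, nbins = bins * bins),
                   nrow = bins, ncol = bins, byrow = TRUE)
  structure(list(counts = counts, edges_a = ja$edges, edges_b = jb$edges,
                 n_voxels = length(R$data)),
            class = "joint_histogram")
}

# Linear rescale to [0, bins) and clamp to 1..bins; returns bin index vector
# plus the bin edges in original units.
bin_indices <- function(x, bins, on_degenerate = "error") {
  lo <- min(x); hi <- max(x)
  if (hi <= lo) {
    if (on_degenerate == "error")
      stop("degenerate intensity range: image is constant", call. = FALSE)
    return(list(bin = rep(1L, length(x)), edges = c(lo, rep(hi, bins))))
  }
  b <- pmin(pmax(floor((x - lo) / (hi - lo) * bins), 0), bins - 1) + 1L
  list(bin = as.integer(b), edges = lo + (hi - lo) * (0:bins) / bins)
}

#' Mutual information of a joint histogram
#'
#' `sum P_ij log(P_ij / (p_i p_j))` over non-empty cells, natural log
#' (nats); non-negative, and equal to the marginal Shannon entropy when the
#' two images are identical.
#'
#' @param h a [joint_histogram()].
#' @return MI in nats.
#' @export
mutual_information <- function(h) {
  if (!inherits(h, "joint_histogram"))
    stop("`h` must be a joint_histogram", call. = FALSE)
  if (h$n_voxels <= 0 || sum(h$counts) == 0)
    stop("empty histogram", call. = FALSE)
  P <- h$counts / sum(h$counts)
  pi_ <- rowSums(P); pj <- colSums(P)
  nz <- which(P > 0, arr.ind = TRUE)
  sum(P[nz] * log(P[nz] / (pi_[nz[, 1]] * pj[nz[, 2]])))
}

marginal_entropy_nats <- function(p) {
  p <- p[p > 0]
  -sum(p * log(p))
}

#' Normalized mutual information cost
#'
#' MI normalized to `[0, 1]` as `MI / max(H_A, H_B)` and returned as the
#' cost `1 - NMI`, so lower is better and identical images score 0.
#'
#' @param R,I [volume()]s on identical grids.
#' @param bins histogram bins.
#' @param value return the NMI value itself instead of the cost.
#' @return Scalar cost in `[0, 1]` (or the NMI value when `value = TRUE`).
#' @export
normalized_mutual_information <- function(R, I, bins = 64L, value = FALSE) {
  h <- joint_histogram(R, I, bins)
  P <- h$counts / sum(h$counts)
  mi <- mutual_information(h)
  hmax <- max(marginal_entropy_nats(rowSums(P)),
              marginal_entropy_nats(colSums(P)))
  nmi <- if (hmax > 0) mi / hmax else 0
  if (value) nmi else 1 - nmi
}

#' Normalized cross-correlation cost
#'
#' Zero-mean, unit-variance Pearson correlation of the paired intensities,
#' returned as the cost `1 - rho` (0 for identical images, 2 for a perfect
#' negative match). The raw unnormalized product sum is available as
#' [cross_correlation_sum()].
#'
#' @param R,I [volume()]s on identical grids; both must be non-constant.
#' @param value return `rho` itself instead of the cost.
#' @return Scalar cost in `[0, 2]` (or `rho` when `value = TRUE`).
#' @export
normalized_cross_correlation <- function(R, I, value = FALSE) {
  stopifnot_volume(R, "R"); stopifnot_volume(I, "I")
  stopifnot_same_grid(R, I)
  a <- as.vector(R$data); b <- as.vector(I$data)
  if (stats::sd(a) == 0 || stats::sd(b) == 0)
    stop("degenerate variance: constant image", call. = FALSE)
  rho <- stats::cor(a, b)
  if (value) rho else 1 - rho
}

#' @rdname normalized_cross_correlation
#' @export
cross_correlation_sum <- function(R, I) {
  stopifnot_volume(R, "R"); stopifnot_volume(I, "I")
  stopifnot_same_grid(R, I)
  sum(R$data * I$data)
}

#' Correlation-ratio cost
#'
#' Measures how well `I` is predicted by a (free) function of `R`:
#' `eta^2 = 1 - E[Var(I | bin(R))] / Var(I)` with `R` partitioned into
#' `bins` intensity classes. The cost `1 - eta^2` lies in `[0, 1]` and is 0
#' at perfect functional dependence.
#'
#' @param R,I [volume()]s on identical grids; `I` must be non-constant.
#' @param bins number of intensity classes for `R`.
#' @return Scalar cost in `[0, 1]`.
#' @export
correlation_ratio <- function(R, I, bins = 64L) {
  stopifnot_volume(R, "R"); stopifnot_volume(I, "I")
  stopifnot_same_grid(R, I)
  cost_cr(as.vector(R$data), as.vector(I$data), as.integer(bins))
}

# vector-level kernels shared with the registration inner loop ------------

cost_cr <- function(a, b, bins) {
  n <- length(b)
  vb <- stats::var(b) * (n - 1) / n
  if (vb == 0) stop("degenerate variance: constant image", call. = FALSE)
  bin <- bin_indices(a, bins, on_degenerate = "single-bin")$bin
  n_k <- tabulate(bin, nbins = bins)
  s1 <- rowsum(b, bin, reorder = TRUE)    # rows are the occupied bins, sorted
  s2 <- rowsum(b^2, bin, reorder = TRUE)
  occ <- n_k[as.integer(rownames(s1))]
  within <- sum(s2 - s1^2 / occ) / n
  max(0, min(1, within / vb))
}

cost_ls <- function(a, b) mean((a - b)^2)

cost_ncc <- function(a, b) {
  sa <- stats::sd(a); sb <- stats::sd(b)
  if (sa == 0 || sb == 0) return(2)  # worst case for degenerate overlap
  1 - stats::cor(a, b)
}

cost_nmi <- function(a, b, bins) {
  ja <- bin_indices(a, bins, on_degenerate = "single-bin")$bin
  jb <- bin_indices(b, bins, on_degenerate = "single-bin")$bin
  counts <- tabulate((ja - 1L) * bins + jb, nbins = bins * bins)
  P <- counts / length(a)
  Pm <- matrix(P, bins, bins, byrow = TRUE)
  pi_ <- rowSums(Pm); pj <- colSums(Pm)
  nz <- which(Pm > 0, arr.ind = TRUE)
  mi <- sum(Pm[nz] * log(Pm[nz] / (pi_[nz[, 1]] * pj[nz[, 2]])))
  hmax <- max(marginal_entropy_nats(pi_), marginal_entropy_nats(pj))
  if (hmax > 0) 1 - mi / hmax else 1
}

# Fixed-range binning: clamp to [lo, hi] set up front (e.g. from the full
# moving image) so bin edges do not move as the overlap region changes.
fixed_bin <- function(x, lo, hi, bins) {
  if (hi <= lo) return(rep(1L, length(x)))
  as.integer(pmin(pmax(floor((x - lo) / (hi - lo) * bins), 0), bins - 1) + 1L)
}

# CR with the reference-side class labels precomputed (labels in 1..bins).
cost_cr_binned <- function(bin, b, bins) {
  n <- length(b)
  vb <- stats::var(b) * (n - 1) / n
  if (vb == 0) return(1)  # constant overlap carries no predictive signal
  n_k <- tabulate(bin, nbins = bins)
  s1 <- rowsum(b, bin, reorder = TRUE)
  s2 <- rowsum(b^2, bin, reorder = TRUE)
  occ <- n_k[as.integer(rownames(s1))]
  within <- sum(s2 - s1^2 / occ) / n
  max(0, min(1, within / vb))
}

# NMI-cost from precomputed bin labels on both sides.
cost_nmi_binned <- function(ja, jb, bins) {
  counts <- tabulate((ja - 1L) * bins + jb, nbins = bins * bins)
  P <- counts / length(ja)
  Pm <- matrix(P, bins, bins, byrow = TRUE)
  pi_ <- rowSums(Pm); pj <- colSums(Pm)
  nz <- which(Pm > 0, arr.ind = TRUE)
  mi <- sum(Pm[nz] * log(Pm[nz] / (pi_[nz[, 1]] * pj[nz[, 2]])))
  hmax <- max(marginal_entropy_nats(pi_), marginal_entropy_nats(pj))
  if (hmax > 0) 1 - mi / hmax else 1
}

# Evaluate a named cost on paired intensity vectors (registration path).
cost_eval_vec <- function(spec, a, b) {
  switch(spec$name,
         LS = cost_ls(a, b),
         CR = cost_cr(a, b, spec$bins),
         NCC = cost_ncc(a, b),
         NMI = cost_nmi(a, b, spec$bins))
}

#' Evaluate a cost between two volumes
#'
#' Convenience dispatcher over the four cost functions.
#'
#' @param R,I [volume()]s on identical grids.
#' @param spec a [cost_spec()].
#' @return Scalar cost (lower is better for all four).
#' @export
cost_eval <- function(R, I, spec = cost_spec("LS")) {
  stopifnot_volume(R, "R"); stopifnot_volume(I, "I")
  stopifnot_same_grid(R, I)
  cost_eval_vec(spec, as.vector(R$data), as.vector(I$data))
}
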