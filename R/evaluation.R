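#' Mean squared error between two volumes
#'
#' `sum((R - I)^2) / (n m l)` over the full grid.
#'
#' @param R,I [volume()]s on identical grids.
#' @return Non-negative scalar.
#' @export
mse_3d <- function(R, I) {
  stopifnot_volume(R, "R"); stopifnot_volume(I, "I")
  stopifnot_same_grid(R, I)
  mean((R$data - I$data)^2)
}

#' Peak signal-to-noise ratio in dB
#'
#' `20 log10(MAX / RMSE)` with `MAX` the maximum intensity of the reference
#' volume by default (set `max_value` for a fixed dynamic range such as
#' 255). Identical volumes give `Inf` with a warning.
#'
#' @param R,I [volume()]s on identical grids.
#' @param max_value peak value; defaults to `max(R$data)`.
#' @return PSNR in dB.
#' @export
psnr <- function(R, I, max_value = NULL) {
  m <- mse_3d(R, I)
  if (is.null(max_value)) max_value <- max(R$data)
  if (m == 0) {
    warning("MSE is zero; PSNR is infinite")
    return(Inf)
  }
  20 * log10(max_value / sqrt(m))
}

#' Shannon entropy of a volume's intensity histogram
#'
#' `-sum p log2 p` over non-empty bins of a `bins`-bin histogram spanning
#' the volume's intensity range, in bits. A constant volume has entropy 0.
#'
#' @param v a [volume()].
#' @param bins histogram bin count (>= 2, default 64).
#' @return Entropy in bits, within `[0, log2(bins)]`.
#' @export
shannon_entropy <- function(v, bins = 64L) {
  stopifnot_volume(v)
  bins <- as.integer(bins)
  if (is.na(bins) || bins < 2L) stop("`bins` must be >= 2", call. = FALSE)
  x <- as.vector(v$data)
  if (max(x) <= min(x)) return(0)
  b <- bin_indices(x, bins)$bin
  p <- tabulate(b, nbins = bins) / length(x)
  p <- p[p > 0]
  -sum(p * log2(p))
}

#' Joint entropy of two volumes
#'
#' Shannon entropy (bits) of the normalized joint histogram. It is at least
#' the larger marginal entropy, at most their sum, and grows with
#' misregistration as the joint histogram disperses.
#'
#' @param R,I [volume()]s on identical grids.
#' @param bins bins per image.
#' @return Joint entropy in bits.
#' @export
joint_entropy <- function(R, I, bins = 64L) {
  h <- joint_histogram(R, I, bins)
  P <- h$counts / sum(h$counts)
  P <- P[P > 0]
  -sum(P * log2(P))
}

#' Voxel-wise subtraction image
#'
#' `R - I` with the reference's grid metadata; energy in the difference
#' concentrates at tissue boundaries when the pair is misaligned.
#'
#' @param R,I [volume()]s on identical grids.
#' @return A [volume()] of differences (intensities may be negative).
#' @export
subtraction_image <- function(R, I) {
  stopifnot_volume(R, "R"); stopifnot_volume(I, "I")
  stopifnot_same_grid(R, I)
  volume(R$data - I$data, spacing = R$spacing, origin = R$origin)
}
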