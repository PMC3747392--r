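make_vol <- function(data) volume(data, spacing = c(1, 1, 1))

test_that("all four costs are minimal for identical images", {
  set.seed(10)
  v <- make_vol(array(runif(8^3, 0, 255), c(8, 8, 8)))
  expect_equal(least_squares(v, v), 0)
  expect_equal(normalized_cross_correlation(v, v), 0, tolerance = 1e-12)
  # binned conditional means leave a little within-bin variance
  expect_lt(correlation_ratio(v, v), 0.01)
  expect_lt(normalized_mutual_information(v, v), 0.02)
})

test_that("least squares equals the mean squared difference", {
  a <- make_vol(array(1:8, c(2, 2, 2)))
  b <- make_vol(array(c(2:8, 10), c(2, 2, 2)))
  expect_equal(least_squares(a, b), mean((1:8 - c(2:8, 10))^2))
})

test_that("joint histogram counts every voxel exactly once", {
  set.seed(2)
  a <- make_vol(array(runif(6^3), c(6, 6, 6)))
  b <- make_vol(array(runif(6^3), c(6, 6, 6)))
  h <- joint_histogram(a, b, bins = 16)
  expect_equal(sum(h$counts), 6^3)
  expect_equal(dim(h$counts), c(16L, 16L))
  expect_equal(length(h$edges_a), 17L)
})

test_that("joint histogram of an image with itself is diagonal", {
  set.seed(3)
  a <- make_vol(array(runif(6^3), c(6, 6, 6)))
  h <- joint_histogram(a, a, bins = 8)
  expect_equal(sum(diag(h$counts)), 6^3)
})

test_that("mutual information matches an explicit double loop", {
  set.seed(4)
  a <- make_vol(array(runif(6^3), c(6, 6, 6)))
  b <- make_vol(array(runif(6^3), c(6, 6, 6)))
  h <- joint_histogram(a, b, bins = 8)
  P <- h$counts / sum(h$counts)
  pi_ <- rowSums(P); pj <- colSums(P)
  mi_ref <- 0
  for (i in 1:8) for (j in 1:8) {
    if (P[i, j] > 0)
      mi_ref <- mi_ref + P[i, j] * log(P[i, j] / (pi_[i] * pj[j]))
  }
  expect_equal(mutual_information(h), mi_ref, tolerance = 1e-13)
})

test_that("mutual information of independent images is near zero", {
  set.seed(5)
  a <- make_vol(array(runif(16^3), c(16, 16, 16)))
  b <- make_vol(array(runif(16^3), c(16, 16, 16)))
  h <- joint_histogram(a, b, bins = 4)
  expect_lt(mutual_information(h), 0.01)
  expect_gt(mutual_information(h), 0)
})

test_that("MI equals the marginal entropy for identical images", {
  set.seed(6)
  a <- make_vol(array(runif(10^3), c(10, 10, 10)))
  h <- joint_histogram(a, a, bins = 16)
  expect_equal(mutual_information(h),
               voxreg:::marginal_entropy_nats(rowSums(h$counts) /
                                                sum(h$counts)),
               tolerance = 1e-12)
  expect_equal(normalized_mutual_information(a, a, 16, value = TRUE), 1,
               tolerance = 1e-12)
})

test_that("NCC is invariant to affine intensity rescaling", {
  set.seed(7)
  a <- make_vol(array(runif(6^3), c(6, 6, 6)))
  b <- make_vol(2.5 * a$data + 7)
  expect_equal(normalized_cross_correlation(a, b), 0, tolerance = 1e-12)
  neg <- make_vol(-a$data)
  expect_equal(normalized_cross_correlation(a, neg), 2, tolerance = 1e-12)
  expect_error(normalized_cross_correlation(a, make_vol(array(1, c(6, 6, 6)))))
})

test_that("cross_correlation_sum is the raw product sum", {
  a <- make_vol(array(1:8, c(2, 2, 2)))
  b <- make_vol(array(8:1, c(2, 2, 2)))
  expect_equal(cross_correlation_sum(a, b), sum((1:8) * (8:1)))
})

test_that("correlation ratio detects functional dependence", {
  set.seed(8)
  a <- make_vol(array(runif(8^3), c(8, 8, 8)))
  b <- make_vol(a$data^2)           # deterministic function of a
  expect_lt(correlation_ratio(a, b, bins = 32), 0.01)
  noise <- make_vol(array(runif(8^3), c(8, 8, 8)))
  expect_gt(correlation_ratio(a, noise, bins = 8), 0.8)
})

test_that("correlation ratio is asymmetric in its arguments", {
  set.seed(9)
  a <- make_vol(array(runif(10^3), c(10, 10, 10)))
  b <- make_vol(abs(a$data - 0.5))  # two-to-one function of a
  expect_lt(correlation_ratio(a, b, bins = 32), 0.05)
  expect_gt(correlation_ratio(b, a, bins = 32), 0.2)
})

test_that("costs degrade monotonically as alignment worsens", {
  v <- generate_phantom(c(24, 24, 24), c(1, 1, 1), seed = 1)
  shift_by <- function(k) {
    tf <- translation_matrix(c(k, 0, 0))
    resample_volume(v, dim(v$data), v$spacing, tf, kernel_spec("trilinear"))
  }
  for (cn in cost_names()) {
    cvals <- vapply(c(0, 2, 5), function(k)
      cost_eval(v, shift_by(k), cost_spec(cn, bins = 32)), numeric(1))
    expect_true(all(diff(cvals) > 0), info = cn)
  }
})

test_that("degenerate inputs are rejected or handled as documented", {
  flat <- make_vol(array(3, c(4, 4, 4)))
  a <- make_vol(array(runif(4^3), c(4, 4, 4)))
  expect_error(joint_histogram(flat, a, 8), "constant")
  h <- joint_histogram(flat, a, 8, on_degenerate = "single-bin")
  expect_equal(sum(h$counts[1, ]), 4^3)
})
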