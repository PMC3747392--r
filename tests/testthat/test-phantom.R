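test_that("phantom generation is deterministic for a fixed seed", {
  a <- generate_phantom(c(16, 16, 16), c(1, 1, 1.3), seed = 7)
  b <- generate_phantom(c(16, 16, 16), c(1, 1, 1.3), seed = 7)
  c_ <- generate_phantom(c(16, 16, 16), c(1, 1, 1.3), seed = 8)
  expect_identical(a$data, b$data)
  expect_false(identical(a$data, c_$data))
})

test_that("phantom contains distinct tissue classes in range [0, 255]", {
  v <- generate_phantom(c(32, 32, 32), c(1, 1, 1.3), seed = 1,
                        texture_sd = 0)
  vals <- sort(unique(as.vector(v$data)))
  expect_true(all(c(0, 40, 130, 180, 220, 240) %in% vals))
  expect_gte(min(v$data), 0)
  expect_lte(max(v$data), 255)
  # background is the most common class, white matter is well represented
  expect_gt(mean(v$data == 0), 0.3)
  expect_gt(mean(v$data == 130), 0.05)
})

test_that("phantom is asymmetric enough to pin down rotations", {
  v <- generate_phantom(c(32, 32, 32), c(1, 1, 1), seed = 1, texture_sd = 0)
  flipped <- v$data[32:1, , ]
  expect_gt(mean((v$data - flipped)^2), 1)
})

test_that("phantom texture does not disturb the seeded RNG stream", {
  set.seed(123)
  before <- .Random.seed
  invisible(generate_phantom(c(12, 12, 12), seed = 99))
  expect_identical(.Random.seed, before)
})

test_that("decimation keeps every k-th slice and scales the spacing", {
  v <- generate_phantom(c(16, 16, 16), c(1, 1, 1.3), seed = 1)
  d <- degrade(v, degradation_spec(subsample_axis = "z", subsample_factor = 2,
                                   rotation_deg = 0,
                                   translation_mm = c(0, 0, 0),
                                   noise_sd = 0, blur_radius = 0))
  expect_equal(dim(d$data), c(16L, 16L, 8L))
  expect_equal(d$spacing, c(1, 1, 2.6))
  expect_equal(d$data[, , 1], v$data[, , 1])
})

test_that("noise injection is seeded and has the requested spread", {
  v <- generate_phantom(c(24, 24, 24), c(1, 1, 1), seed = 1, texture_sd = 0)
  spec <- degradation_spec(subsample_factor = 1, rotation_deg = 0,
                           translation_mm = c(0, 0, 0), noise_sd = 10,
                           blur_radius = 0, seed = 5)
  d1 <- degrade(v, spec)
  d2 <- degrade(v, spec)
  expect_identical(d1$data, d2$data)
  resid <- d1$data - v$data
  expect_lt(abs(stats::sd(resid) - 10), 0.5)
  expect_lt(abs(mean(resid)), 0.5)
})

test_that("blurring reduces high-frequency content without moving the mean", {
  v <- generate_phantom(c(24, 24, 24), c(1, 1, 1), seed = 1)
  spec <- degradation_spec(subsample_factor = 1, rotation_deg = 0,
                           translation_mm = c(0, 0, 0), noise_sd = 0,
                           blur_radius = 5)
  d <- degrade(v, spec)
  expect_lt(stats::sd(d$data), stats::sd(v$data))
  expect_lt(abs(mean(d$data) - mean(v$data)), 2)
})

test_that("pure translation shifts the center of mass by the translation", {
  v <- generate_phantom(c(32, 32, 32), c(1, 1, 1), seed = 1, texture_sd = 0)
  spec <- degradation_spec(subsample_factor = 1, rotation_deg = 0,
                           translation_mm = c(2, 3, 0), noise_sd = 0,
                           blur_radius = 0)
  d <- degrade(v, spec)
  shift <- center_of_mass(d) - center_of_mass(v)
  # degrade() moves the content by +t, so the recovered registration
  # parameters are directly comparable to the degradation parameters
  expect_equal(as.vector(shift), c(2, 3, 0), tolerance = 0.2)
})

test_that("the full degradation chain reproduces its documented defaults", {
  spec <- degradation_spec()
  expect_equal(spec$subsample_axis, "z")
  expect_equal(spec$subsample_factor, 2L)
  expect_equal(spec$rotation_deg, 5)
  expect_equal(spec$translation_mm, c(2, 3, 0))
  expect_equal(spec$blur_radius, 5)
  expect_equal(spec$noise_sd, 10)
  v <- generate_phantom(c(16, 16, 16), c(1, 1, 1.3), seed = 1)
  d <- degrade(v, spec)
  expect_equal(dim(d$data), c(16L, 16L, 8L))
})
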