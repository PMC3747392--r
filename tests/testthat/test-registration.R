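test_that("coarse rotation grid is the full cartesian product", {
  g <- coarse_rotation_grid()
  expect_equal(dim(g), c(125L, 3L))
  for (j in 1:3)
    expect_setequal(unique(g[, j]), c(-30, -15, 0, 15, 30))
  expect_equal(nrow(unique(g)), 125L)
  g2 <- coarse_rotation_grid(c(-10, 0, 10))
  expect_equal(dim(g2), c(27L, 3L))
})

test_that("candidate retention keeps the best fifth, sorted by cost", {
  entries <- lapply(sample(1:125), function(k)
    list(params = k, cost = as.double(k)))
  cs <- candidate_set(entries, retained_fraction = 0.2)
  kept <- retain_top_fraction(cs)
  expect_equal(length(kept$entries), 25L)
  costs <- vapply(kept$entries, `[[`, numeric(1), "cost")
  expect_equal(costs, as.double(1:25))
  kept2 <- retain_top_fraction(candidate_set(kept$entries, 0.2))
  expect_equal(length(kept2$entries), 5L)
})

test_that("free parameter sets grow with the declared DOF", {
  expect_equal(free_names_for_dof(3), c("t1", "t2", "t3"))
  expect_equal(free_names_for_dof(4), c("t1", "t2", "t3", "sg"))
  expect_length(free_names_for_dof(6), 6)
  expect_length(free_names_for_dof(7), 7)
  expect_length(free_names_for_dof(9), 9)
  expect_length(free_names_for_dof(12), 12)
  expect_error(free_names_for_dof(5))
})

test_that("center of mass is exact for a point mass", {
  a <- array(0, c(9, 9, 9))
  a[3, 5, 7] <- 100
  v <- volume(a, spacing = c(1, 1, 2), origin = c(10, 0, 0))
  expect_equal(as.vector(center_of_mass(v, threshold = 0)),
               c(10 + 2, 4, 12))
})

test_that("coordinate descent minimizes a separable quadratic", {
  f <- function(p) {
    (p$translation[1] - 3)^2 + (p$translation[2] + 2)^2 +
      (p$rotation[1] - 10)^2
  }
  res <- local_optimize(f, dof_params(dof = 6), dof = 6,
                        steps = optim_steps(), max_evals = 2000)
  expect_lt(res$cost, 0.05)
  expect_equal(res$params$translation[1], 3, tolerance = 0.15)
  expect_equal(res$params$rotation[1], 10, tolerance = 0.15)
  expect_true(all(diff(res$trace) <= 0))
})

test_that("coordinate descent respects its evaluation budget", {
  calls <- 0
  f <- function(p) { calls <<- calls + 1; sum(p$translation^2) }
  res <- local_optimize(f, dof_params(translation = c(30, -20, 10), dof = 3),
                        dof = 3, max_evals = 40)
  expect_lte(res$n_evals, 40)
  expect_lte(calls, 41)
})

test_that("pyramid levels shrink dims and keep world extent", {
  v <- generate_phantom(c(32, 32, 32), c(1, 1, 1), seed = 1)
  pyr <- build_pyramid(v, factors = c(4, 2, 1))
  expect_named(pyr, c("4", "2", "1"))
  expect_equal(dim(pyr[["4"]]$data), c(8L, 8L, 8L))
  expect_equal(pyr[["4"]]$spacing, c(4, 4, 4))
  expect_identical(pyr[["1"]]$data, v$data)
  # world extent (dim * spacing) is preserved across levels
  expect_equal(dim(pyr[["4"]]$data) * pyr[["4"]]$spacing,
               dim(pyr[["1"]]$data) * pyr[["1"]]$spacing)
})

test_that("translation-only misalignment is recovered at small scale", {
  ref <- generate_phantom(c(24, 24, 24), c(1, 1, 1), seed = 2,
                          texture_sd = 0)
  mov <- degrade(ref, degradation_spec(subsample_factor = 1,
                                       rotation_deg = 0,
                                       translation_mm = c(2, -1, 0),
                                       noise_sd = 0, blur_radius = 0))
  r <- register_volumes(ref, mov, cost = cost_spec("LS"),
                        kernel = kernel_spec("trilinear"), max_dof = 6)
  expect_lt(max(abs(r$final_params$translation - c(2, -1, 0))), 0.5)
  expect_lt(max(abs(r$final_params$rotation)), 1.5)
  expect_equal(r$final_params$dof, 6L)
})

test_that("registration traces record the search combinatorics", {
  ref <- generate_phantom(c(24, 24, 24), c(1, 1, 1), seed = 2,
                          texture_sd = 0)
  mov <- degrade(ref, degradation_spec(subsample_factor = 1,
                                       rotation_deg = 3,
                                       translation_mm = c(1, 0, 0),
                                       noise_sd = 0, blur_radius = 0))
  r <- register_volumes(ref, mov, cost = cost_spec("LS"),
                        kernel = kernel_spec("trilinear"), max_dof = 12)
  tr <- r$level_traces
  expect_equal(tr$level8$n_initial, 125L)
  expect_equal(tr$level8$n_retained, c(25L, 5L))
  expect_equal(tr$level2$dof_chain, c(7L, 9L, 12L))
  expect_equal(tr$level1$dof, 12L)
  expect_gt(tr$level8$n_evals, 125)     # at least one eval per config
  expect_equal(r$n_evals,
               tr$level8$n_evals + tr$level4$n_evals + tr$level2$n_evals +
                 tr$level1$n_evals)
  expect_s3_class(r$final_transform, "affine_transform")
})

test_that("apply_registration reformats the moving image onto the reference grid", {
  ref <- generate_phantom(c(20, 20, 20), c(1, 1, 1), seed = 4,
                          texture_sd = 0)
  mov <- degrade(ref, degradation_spec(subsample_factor = 1,
                                       rotation_deg = 0,
                                       translation_mm = c(3, 0, 0),
                                       noise_sd = 0, blur_radius = 0))
  r <- register_volumes(ref, mov, cost = cost_spec("LS"),
                        kernel = kernel_spec("trilinear"), max_dof = 6)
  reg <- apply_registration(r, mov, ref, kernel_spec("trilinear"))
  expect_equal(dim(reg$data), dim(ref$data))
  expect_lt(mse_3d(ref, reg), mse_3d(ref, mov))
})

test_that("invalid registration inputs are rejected", {
  v <- generate_phantom(c(12, 12, 12), seed = 1)
  expect_error(register_volumes(v, v, max_dof = 5), "max_dof")
  expect_error(register_volumes(v, v, cost = "LS"), "cost_spec")
})
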