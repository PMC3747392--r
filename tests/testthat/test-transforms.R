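test_that("elementary transforms act as expected on points", {
  expect_equal(as.vector(apply_transform(translation_matrix(c(2, 3, 0)),
                                         c(1, 1, 1))), c(3, 4, 1))
  expect_equal(as.vector(apply_transform(scaling_matrix(c(2, 1, 1)),
                                         c(3, 5, 7))), c(6, 5, 7))
  expect_equal(as.vector(apply_transform(rotation_matrix("z", 90),
                                         c(1, 0, 0))), c(0, 1, 0),
               tolerance = 1e-12)
  expect_equal(as.vector(apply_transform(rotation_matrix("x", 90),
                                         c(0, 1, 0))), c(0, 0, 1),
               tolerance = 1e-12)
  expect_equal(as.vector(apply_transform(shear_matrix(c(0.5, 0, 0)),
                                         c(0, 2, 0))), c(1, 2, 0))
})

test_that("rotations are proper and orthogonal", {
  for (ax in c("x", "y", "z")) {
    R <- unclass(rotation_matrix(ax, 37))[1:3, 1:3]
    expect_equal(t(R) %*% R, diag(3), tolerance = 1e-12)
    expect_equal(det(R), 1, tolerance = 1e-12)
  }
})

test_that("affine transforms preserve collinearity", {
  tf <- params_to_matrix(dof_params(c(2, -1, 3), c(10, -5, 20),
                                    c(1.1, 0.9, 1), c(0.1, 0, -0.05)),
                         center = c(5, 5, 5))
  p1 <- c(0, 0, 0); p2 <- c(1, 2, 3)
  mid <- (p1 + p2) / 2
  q <- apply_transform(tf, rbind(p1, p2, mid))
  expect_equal(as.vector(q[3, ]), as.vector((q[1, ] + q[2, ]) / 2),
               tolerance = 1e-12)
})

test_that("parameter round trip through matrix form is exact", {
  p <- dof_params(translation = c(2, 3, -1), rotation = c(5, -10, 25),
                  scale = c(1.05, 0.9, 1.2), shear = c(0.1, -0.05, 0.02))
  ctr <- c(31.5, 31.5, 41)
  tf <- params_to_matrix(p, ctr)
  q <- matrix_to_params(tf, ctr)
  expect_equal(q$translation, p$translation, tolerance = 1e-9)
  expect_equal(q$rotation, p$rotation, tolerance = 1e-9)
  expect_equal(q$scale, p$scale, tolerance = 1e-9)
  expect_equal(q$shear, p$shear, tolerance = 1e-9)
})

test_that("dof_params enforces neutrality beyond the declared DOF", {
  expect_error(dof_params(rotation = c(5, 0, 0), dof = 3))
  expect_error(dof_params(scale = c(1.1, 1, 1), dof = 6))
  expect_error(dof_params(scale = c(1.1, 1.2, 1.1), dof = 7))
  expect_error(dof_params(shear = c(0.1, 0, 0), dof = 9))
  expect_silent(dof_params(scale = 1.1, dof = 7))
})

test_that("neutral parameters give the identity matrix", {
  tf <- params_to_matrix(dof_params(), center = c(10, 20, 30))
  expect_equal(unclass(tf), diag(4), tolerance = 1e-12)
})

test_that("transform text and JSON round trips are lossless", {
  tf <- params_to_matrix(dof_params(c(1, 2, 3), c(4, 5, 6)), c(0, 0, 0))
  path <- tempfile(fileext = ".mat")
  on.exit(unlink(path))
  write_transform(tf, path)
  expect_equal(unclass(read_transform(path)), unclass(tf),
               tolerance = 1e-10)
  p <- dof_params(c(1, 2, 3), c(4, 5, 6), 1.1, c(0, 0.1, 0), dof = 12)
  jp <- tempfile(fileext = ".json")
  on.exit(unlink(jp), add = TRUE)
  write_transform_json(p, jp)
  q <- read_transform_json(jp)
  expect_equal(q$translation, p$translation)
  expect_equal(q$rotation, p$rotation)
  expect_equal(q$scale, p$scale)
})
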