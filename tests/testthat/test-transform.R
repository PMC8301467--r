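test_that("rotation matrices are orthonormal and invert exactly", {
  set.seed(3)
  for (i in 1:20) {
    ang <- runif(3, -80, 80)
    R <- mandimorph:::rotation_matrix(ang)
    expect_lt(max(abs(t(R) %*% R - diag(3))), 1e-9)
    expect_equal(det(R), 1, tolerance = 1e-9)
    # angle decomposition inverts the construction away from gimbal lock
    expect_equal(mandimorph:::rotation_angles(R), ang, tolerance = 1e-6)
  }
})

test_that("compose(T, invert(T)) is the identity on points", {
  set.seed(4)
  pts <- matrix(rnorm(30, 0, 10), ncol = 3)
  for (i in 1:10) {
    t1 <- rigid_transform(runif(3, -40, 40), runif(3, -8, 8), runif(3, -5, 5))
    ident <- compose_transform(t1, invert_transform(t1))
    expect_lt(max(abs(transform_points(ident, pts) - pts)), 1e-6)
    # composition acts like sequential application
    t2 <- rigid_transform(runif(3, -30, 30), runif(3, -5, 5), runif(3, -5, 5))
    expect_equal(transform_points(compose_transform(t1, t2), pts),
                 transform_points(t1, transform_points(t2, pts)),
                 tolerance = 1e-8)
  }
})

test_that("apply_transform: identity is voxel-identical, whole-voxel NN shift is exact", {
  set.seed(5)
  v <- volume(array(runif(8 * 7 * 6, 0, 1000), c(8, 7, 6)), 0.5)
  out <- apply_transform(v, rigid_transform(), v)
  expect_equal(out$data, v$data, tolerance = 1e-12)

  sh <- apply_transform(v, rigid_transform(translation_mm = c(1, 0, 0)), v,
                        interpolation = "nearest", background = -1)
  # content shifted by 2 voxels along +x, intensities preserved exactly
  expect_identical(sh$data[3:8, , ], v$data[1:6, , ])
  expect_true(all(sh$data[1:2, , ] == -1))
})

test_that("rotation round trip stays below the interpolation tolerance", {
  ph <- rat_left_030()
  v <- ph$volume
  ctr <- v$origin + (dim(v$data) - 1) / 2 * v$spacing
  t4 <- rigid_transform(c(4, 0, 0), c(0, 0, 0), ctr)
  fwd <- apply_transform(v, t4, v)
  back <- apply_transform(fwd, invert_transform(t4), v)
  inside <- v$data > 0 & back$data > 0
  mad <- mean(abs(back$data[inside] - v$data[inside]))
  # documented interpolation tolerance: 5% of the dynamic range
  expect_lt(mad, 0.05 * diff(range(v$data)))
})

test_that("transform JSON files round trip", {
  t1 <- rigid_transform(c(1.5, -2, 4), c(0.25, -0.5, 1), c(3, 2, 1))
  path <- file.path(tempdir(), "t.json")
  write_transform(t1, path)
  t2 <- read_transform(path)
  expect_equal(t2$angles_deg, t1$angles_deg)
  expect_equal(t2$translation_mm, t1$translation_mm)
  expect_equal(t2$center_mm, t1$center_mm)
  unlink(path)
})
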