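test_that("volume constructor enforces its invariants", {
  expect_error(volume(matrix(0, 2, 2), 1), "3D")
  expect_error(volume(array(0, c(2, 2, 2)), c(1, -1, 1)), "positive")
  expect_error(volume(array(0, c(2, 2, 2)), 1, c(0, NA, 0)), "finite")
  v <- volume(array(1:8, c(2, 2, 2)), 0.5, c(1, 2, 3))
  expect_identical(dim(v), c(2L, 2L, 2L))
  expect_equal(voxel_to_physical(v, c(1, 1, 1))[1, ], c(1.5, 2.5, 3.5))
  expect_equal(physical_to_voxel(v, c(1.5, 2.5, 3.5))[1, ], c(1, 1, 1))
})

test_that("crop preserves physical coordinates and rejects bad boxes", {
  set.seed(1)
  v <- volume(array(rnorm(6 * 5 * 4), c(6, 5, 4)), c(0.5, 0.4, 0.3), c(1, -2, 0))
  full <- crop(v, bounding_box(c(0, 0, 0), dim(v)))
  expect_identical(full$data, v$data)
  expect_identical(full$origin, v$origin)

  # a marked voxel keeps its physical position under nested crops
  v$data[4, 3, 2] <- 99
  b1 <- crop(v, bounding_box(c(2, 1, 0), c(6, 5, 4)))
  idx1 <- which(b1$data == 99, arr.ind = TRUE) - 1L
  expect_equal(voxel_to_physical(b1, idx1)[1, ],
               voxel_to_physical(v, c(3, 2, 1))[1, ])
  b2 <- crop(b1, bounding_box(c(0, 0, 0), c(3, 3, 3)))
  idx2 <- which(b2$data == 99, arr.ind = TRUE) - 1L
  expect_equal(voxel_to_physical(b2, idx2)[1, ],
               voxel_to_physical(v, c(3, 2, 1))[1, ])

  expect_error(bounding_box(c(0, 0, 0), c(0, 2, 2)), "empty")
  expect_error(crop(v, bounding_box(c(0, 0, 0), c(7, 5, 4))), "exceeds")
})

test_that("binarize thresholds and commutes with crop", {
  set.seed(2)
  v <- volume(array(runif(5 * 5 * 5, 0, 100), c(5, 5, 5)), 1)
  expect_true(all(binarize(v, 101)$data == 0))
  m1 <- binarize(v, 30)$data
  m2 <- binarize(v, 60)$data
  expect_true(all(m2 <= m1))            # monotone nesting of masks
  box <- bounding_box(c(1, 0, 2), c(4, 3, 5))
  expect_identical(crop(binarize(v, 50), box)$data,
                   binarize(crop(v, box), 50)$data)
})

test_that("extract_surface matches enumeration on canonical shapes", {
  cube <- array(0, c(5, 5, 5))
  cube[2:4, 2:4, 2:4] <- 1
  v <- volume(cube, 1)
  s <- extract_surface(v)
  # oracle: brute-force 6-neighbour check
  oracle <- array(0, c(5, 5, 5))
  for (i in 2:4) for (j in 2:4) for (k in 2:4) {
    nb <- c(cube[i - 1, j, k], cube[i + 1, j, k], cube[i, j - 1, k],
            cube[i, j + 1, k], cube[i, j, k - 1], cube[i, j, k + 1])
    if (any(nb == 0)) oracle[i, j, k] <- 1
  }
  expect_identical(s$data, oracle)
  expect_equal(sum(s$data), 26)

  single <- array(0, c(3, 3, 3)); single[2, 2, 2] <- 1
  expect_identical(extract_surface(volume(single, 1))$data, single)

  # a hollow shell is a fixed point of surface extraction
  expect_identical(extract_surface(s)$data, s$data)

  empty <- volume(array(0, c(3, 3, 3)), 1)
  expect_equal(sum(extract_surface(empty)$data), 0)
})

test_that("label_components separates disjoint blocks", {
  a <- array(0, c(6, 4, 4))
  a[1:2, , ] <- 1
  a[5:6, , ] <- 1
  lab <- label_components(volume(a, 1))
  expect_equal(attr(lab, "n_components"), 2)
  expect_equal(length(unique(lab$data[a == 1])), 2)
  expect_true(all(lab$data[a == 0] == 0))
})
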