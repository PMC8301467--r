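test_that("phantom spec validation rejects unresolvable geometry", {
  expect_error(phantom_spec("rat", voxel_mm = 0.9), "tube radius")
  expect_error(phantom_spec("rat", noise_sd = -1), "noise_sd")
  expect_error(phantom_spec("rat", incisor = list(bevel_deg = 95)), "bevel")
  expect_error(phantom_spec("rat", incisor = list(bevel_deg = 5)), "shallow")
  expect_error(phantom_spec("rat", incisor = list(r_tube = 9)), "self-intersect")
})

test_that("mirrored construction gives exactly equal ground truth and voxels", {
  ph <- rat_both_015()
  tl <- ph$truth$sides$left; tr <- ph$truth$sides$right
  expect_identical(tl$labial_mm, tr$labial_mm)
  expect_identical(tl$lingual_mm, tr$lingual_mm)
  expect_identical(tl$occlusal_mm, tr$occlusal_mm)
  expect_identical(tl$occlusal_angle_deg, tr$occlusal_angle_deg)
  # the noise-free voxel grid itself is mirror symmetric about x = 0
  d <- ph$volume$data
  expect_identical(d, d[dim(d)[1]:1, , ])
})

test_that("a crown elongation shifts the labial ground truth exactly", {
  base <- phantom_spec("rat", voxel_mm = 0.3)
  long <- phantom_spec("rat", voxel_mm = 0.3,
                       incisor = list(left = list(crown_labial_mm = 12.66 + 2.3)))
  t0 <- mandimorph:::phantom_truth(base)
  t1 <- mandimorph:::phantom_truth(long)
  expect_equal(t1$sides$left$labial_mm - t1$sides$right$labial_mm, 2.3)
  expect_identical(t1$sides$right$labial_mm, t0$sides$right$labial_mm)
})

test_that("ground truth is voxel-size independent and matches numeric oracles", {
  s1 <- phantom_spec("rat", voxel_mm = 0.2)
  s2 <- phantom_spec("rat", voxel_mm = 0.05)
  expect_identical(mandimorph:::phantom_truth(s1)$sides,
                   mandimorph:::phantom_truth(s2)$sides)

  # quarter-circle crown: labial surface radius 10 mm spanning 90 degrees
  qs <- phantom_spec("rat", voxel_mm = 0.3,
                     incisor = list(R = 9.5, r_tube = 0.5,
                                    crown_labial_mm = pi / 2 * 10,
                                    theta_alv_deg = 2, bevel_deg = 40))
  it <- mandimorph:::incisor_truth(qs$incisor$left, qs$geometry$body_y[2])
  expect_equal(it$theta_tip - it$theta_alv_out, pi / 2, tolerance = 1e-12)
  # numeric arc-length integration along the labial offset curve
  th <- seq(it$theta_alv_out, it$theta_tip, length.out = 20001)
  curve <- cbind(it$center[1] + it$A * sin(th), it$center[2] - it$A * cos(th))
  num_len <- sum(sqrt(rowSums(diff(curve)^2)))
  expect_equal(num_len, 15.70796, tolerance = 1e-3)
  expect_equal(it$labial_mm, pi / 2 * 10, tolerance = 1e-12)

  # occlusal facet length: numeric root of the lingual-circle crossing
  f <- function(s) sqrt(sum((it$tip + s * it$facet_u - it$center)^2)) - it$B
  # bracket between the tip (outside the lingual circle) and the chord
  # midpoint (inside it when the facet reaches the lingual surface)
  s_num <- stats::uniroot(f, c(1e-6, it$A * sin(40 * pi / 180)),
                          tol = 1e-12)$root
  expect_equal(it$occlusal_mm, s_num, tolerance = 1e-9)
  # gnaw-ridge angle consistency: lingual arc length from the ridge point
  g_num <- it$tip + s_num * it$facet_u
  th_g <- atan2(g_num[1] - it$center[1], it$center[2] - g_num[2])
  expect_equal(it$lingual_mm, it$B * (th_g - it$theta_alv_in), tolerance = 1e-9)
})

test_that("apply_defect removes an analytically known sphere volume", {
  vol <- bone_block(0.1)
  mask <- binarize(vol, 500)
  res <- apply_defect(vol, mask, defect_spec("CSD", "left"))
  analytic <- 4 / 3 * pi * 2.5^3
  expect_lt(abs(res$removed_mm3 - analytic) / analytic, 0.02)
  # voxels outside the sphere are untouched
  changed <- which(res$volume$data != vol$data)
  d <- dim(vol$data)
  ijk <- cbind((changed - 1) %% d[1],
               ((changed - 1) %/% d[1]) %% d[2],
               (changed - 1) %/% (d[1] * d[2]))
  pts <- voxel_to_physical(vol, ijk)
  ctr <- c(5, -5, 5)
  expect_lte(max(sqrt(rowSums(sweep(pts, 2, ctr, `-`)^2))), 2.5 + 1e-9)
})

test_that("defect modes produce the documented component counts", {
  ph <- rat_both_015()
  mask <- binarize(ph$volume, 500)

  none <- apply_defect(ph$volume, mask, defect_spec("none"))
  expect_identical(none$volume$data, ph$volume$data)
  expect_equal(none$removed_mm3, 0)

  cro <- apply_defect(ph$volume, mask, defect_spec("CRO_wide", "left"))
  expect_equal(cro$component_count, 2)   # body separated from ramus
  expect_gt(cro$removed_mm3, 0)
  cro_n <- apply_defect(ph$volume, mask, defect_spec("CRO_narrow", "left"))
  expect_equal(cro_n$component_count, 2)
  expect_lt(cro_n$removed_mm3, cro$removed_mm3)

  id <- apply_defect(ph$volume, mask, defect_spec("ID", "left"))
  expect_equal(id$component_count, 1)    # dorsal strut intact
  csd <- apply_defect(ph$volume, mask, defect_spec("CSD", "left"))
  expect_equal(csd$component_count, 1)

  # contralateral side untouched by a left defect
  xs <- ph$volume$origin[1] + (seq_len(dim(ph$volume$data)[1]) - 1) *
    ph$volume$spacing[1]
  right <- xs < 0
  expect_identical(cro$volume$data[right, , ], ph$volume$data[right, , ])
})

test_that("perturb_pose resamples under rigid motion", {
  ph <- rat_left_030()
  v <- ph$volume
  ident <- perturb_pose(v, rigid_transform())
  expect_equal(ident$data, v$data, tolerance = 1e-12)

  # whole-voxel translation with nearest-neighbour sampling is a pure shift
  sh <- perturb_pose(v, rigid_transform(translation_mm = c(0, 2 * 0.3, 0)),
                     interpolation = "nearest")
  expect_identical(sh$data[, 3:dim(v$data)[2], ], v$data[, 1:(dim(v$data)[2] - 2), ])

  # 4-degree rotation round trip stays below the interpolation tolerance
  ctr <- v$origin + (dim(v$data) - 1) / 2 * v$spacing
  t4 <- rigid_transform(c(0, 4, 0), c(0, 0, 0), ctr)
  fwd <- perturb_pose(v, t4)
  back <- apply_transform(fwd, invert_transform(t4), v)
  inside <- v$data > 0 & back$data > 0
  expect_lt(mean(abs(back$data[inside] - v$data[inside])),
            0.05 * diff(range(v$data)))

  # documented capture-range cap
  expect_error(perturb_pose(v, rigid_transform(c(15, 0, 0))), "capture range")
  # seeded random poses are reproducible and within the caps
  p1 <- perturb_pose(v, seed = 9)
  p2 <- perturb_pose(v, seed = 9)
  expect_identical(p1$data, p2$data)
  expect_true(all(abs(attr(p1, "applied_pose")$angles_deg) <= 10))
})
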