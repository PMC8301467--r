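test_that("occlusal plane fit matches closed forms and is rotation equivariant", {
  set.seed(8)
  xy <- cbind(runif(30, -5, 5), runif(30, -5, 5))
  flat <- cbind(xy, 0)
  pl <- fit_occlusal_plane(flat)
  expect_equal(pl$normal, c(0, 0, 1), tolerance = 1e-9)
  expect_lt(max(abs((flat - matrix(pl$point, 30, 3, byrow = TRUE)) %*% pl$normal)),
            1e-9)

  tilted <- cbind(xy, 0.1 * xy[, 1])    # plane z = 0.1 x
  pl2 <- fit_occlusal_plane(tilted)
  expect_equal(pl2$normal, c(-0.1, 0, 1) / sqrt(1.01), tolerance = 1e-9)

  for (i in 1:5) {
    R <- mandimorph:::rotation_matrix(runif(3, -20, 20))
    plr <- fit_occlusal_plane(tilted %*% t(R))
    expect_equal(abs(sum(plr$normal * (R %*% pl2$normal))), 1, tolerance = 1e-9)
  }
  expect_error(fit_occlusal_plane(cbind(1:5, 2 * (1:5), 3 * (1:5))),
               "collinear|degenerate")
  expect_error(fit_occlusal_plane(flat[1:2, ]), "3 points")
})

test_that("reorientation recovers a tilted occlusal plane", {
  ph <- rat_both_015()
  v <- ph$volume
  pts0 <- occlusal_surface_points(v)
  pl0 <- fit_occlusal_plane(pts0)
  reo0 <- reorient_to_occlusal(v, pl0)
  expect_lt(max(abs(reo0$transform$angles_deg)), 0.2)   # already horizontal

  ctr <- v$origin + (dim(v$data) - 1) / 2 * v$spacing
  tilt <- rigid_transform(c(8, 0, 0), c(0, 0, 0), ctr)
  tilted <- perturb_pose(v, tilt)
  pl1 <- fit_occlusal_plane(occlusal_surface_points(tilted))
  expect_gt(acos(pl1$normal[3]) * 180 / pi, 7)          # tilt visible
  reo1 <- reorient_to_occlusal(tilted, pl1)
  pl2 <- fit_occlusal_plane(occlusal_surface_points(reo1$volume))
  expect_lt(acos(min(pl2$normal[3], 1)) * 180 / pi, 0.5)
  # idempotence: a second reorientation is (near) the identity
  reo2 <- reorient_to_occlusal(reo1$volume, pl2)
  expect_lt(max(abs(reo2$transform$angles_deg)), 0.5)
})

test_that("path_length and occlusal_angle work on analytic profiles", {
  pr <- sagittal_profile(rbind(c(0, 0), c(3, 4)),
                         list(alveolus_edge = 1, tip = 2))
  expect_equal(path_length(pr, "labial"), 5)
  expect_error(path_length(pr, "lingual"), "gnaw")
  expect_error(occlusal_angle(pr), "gnaw")

  # quarter circle r = 10 sampled at 0.5 degrees
  th <- seq(0, pi / 2, by = 0.5 * pi / 180)
  qc <- cbind(10 * cos(th), 10 * sin(th))
  prq <- sagittal_profile(qc, list(alveolus_edge = 1, tip = length(th)))
  expect_equal(path_length(prq, "labial"), pi * 10 / 2, tolerance = 0.01)

  # 30-degree facet from tip (2, 2 tan30) down to ridge (0, 0):
  # signed positive because the tip is dorsal to the ridge
  s <- seq(2, 0, length.out = 20)
  prf <- sagittal_profile(rbind(c(-1, -1), cbind(s, s * tan(30 * pi / 180))),
                          list(alveolus_edge = 1, tip = 2, gnaw_ridge = 21))
  expect_equal(occlusal_angle(prf), 30, tolerance = 1e-6)

  flatf <- sagittal_profile(rbind(c(-1, -1), cbind(seq(2, 0, length.out = 10), 0)),
                            list(alveolus_edge = 1, tip = 2, gnaw_ridge = 11))
  expect_equal(occlusal_angle(flatf), 0, tolerance = 1e-9)

  expect_error(sagittal_profile(qc, list(alveolus_edge = 5, tip = 2)), "ordered")
  expect_error(sagittal_profile(qc[1, , drop = FALSE],
                                list(alveolus_edge = 1, tip = 1)), "2 points")
})

test_that("phantom incisor metrics agree with ground truth within 2 voxel edges", {
  ph <- rat_left_012()
  v <- 0.12
  tr <- ph$truth$sides$left
  pr <- extract_sagittal_profile(ph$volume, "left")
  expect_lt(abs(path_length(pr, "labial") - tr$labial_mm), 2 * v)
  expect_lt(abs(path_length(pr, "lingual") - tr$lingual_mm), 2 * v)
  expect_lt(abs(path_length(pr, "occlusal") - tr$occlusal_mm), 2 * v)
  expect_lt(abs(occlusal_angle(pr) - tr$occlusal_angle_deg), 1)
  # labial span contains the occlusal bevel span
  expect_gte(path_length(pr, "labial"), path_length(pr, "occlusal"))
  # landmark ordering invariant
  lm <- pr$landmarks
  expect_true(lm$alveolus_edge < lm$tip && lm$tip < lm$gnaw_ridge &&
              lm$gnaw_ridge < lm$alveolus_edge_lingual)
  expect_error(extract_sagittal_profile(ph$volume, "right"), "right")
})

test_that("mirrored phantom sides measure equal within a voxel edge", {
  ph <- rat_both_015()
  m <- measure_incisors(ph$volume)
  for (met in unique(m$metric)) {
    l <- m$value[m$metric == met & m$side == "left"]
    r <- m$value[m$metric == met & m$side == "right"]
    tol <- if (met == "occlusal_angle") 0.5 else 0.15
    expect_lt(abs(l - r), tol)
  }
})

test_that("cheek tooth heights recover the preset crown heights", {
  ph <- rabbit_both_020()
  hts <- ph$truth$sides$left$cheek_heights_mm
  # rabbit cheek tooth #2 baseline height 5.3 mm
  h2 <- cheek_tooth_height(ph$volume, "#2", "left")
  expect_equal(h2$height_mm, 5.3, tolerance = 2 * 0.2)
  expect_equal(h2$tooth_label, "#2")
  for (k in seq_along(hts)) {
    hk <- cheek_tooth_height(ph$volume, k, "right")
    expect_equal(hk$height_mm, unname(hts[k]), tolerance = 2 * 0.2)
  }
  expect_error(cheek_tooth_height(ph$volume, "#9", "left"), "not found")
})
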