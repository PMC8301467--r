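test_that("cohort simulation honours its noise model", {
  # zero difference SD: left equals right for every animal and timepoint
  p0 <- cohort_params("rat", n = 6, metrics = list(
    labial = list(sd_diff = 0), lingual = list(sd_diff = 0),
    occlusal = list(sd_diff = 0)), defect_side = "none", seed = 5)
  tab <- simulate_cohort(p0)
  w <- reshape(tab, direction = "wide", idvar = c("animal_id", "timepoint", "metric"),
               timevar = "side", drop = c("species", "units"))
  expect_equal(w$value.left, w$value.right)

  # fixed seed: identical tables
  p1 <- cohort_params("rat", n = 8, seed = 11)
  expect_identical(simulate_cohort(p1), simulate_cohort(p1))

  expect_error(cohort_params("rat", metrics = list(labial = list(sd_diff = -1))),
               "negative SD")
  expect_error(cohort_params("rat", n = 1), "n >= 2")
})

test_that("simulated metrics match the configured baseline moments", {
  p <- cohort_params("rat", n = 20000, timepoints = "baseline",
                     defect_side = "none", seed = 21)
  tab <- simulate_cohort(p)
  lab <- tab[tab$metric == "labial" & tab$side == "left", "value"]
  se <- sqrt(0.59^2 + 0.6^2 / 4) / sqrt(20000)
  expect_lt(abs(mean(lab) - 12.66), 3 * se)

  # left-right difference SD converges to the configured value (< 5% error)
  p2 <- cohort_params("rat", n = 100000, timepoints = "baseline",
                      defect_side = "none",
                      metrics = list(lingual = NULL, occlusal = NULL),
                      seed = 22)
  tab2 <- simulate_cohort(p2)
  dl <- tab2[tab2$side == "left", "value"] - tab2[tab2$side == "right", "value"]
  expect_lt(abs(sd(dl) - 0.6) / 0.6, 0.05)
})

test_that("defect effects land on the defect side at post-baseline timepoints", {
  p <- cohort_params("rat", n = 2000, timepoints = c("baseline", "wk3"),
                     defect_side = "left", seed = 31)
  tab <- simulate_cohort(p)
  lab <- tab[tab$metric == "labial", ]
  d_base <- mean(lab$value[lab$side == "left" & lab$timepoint == "baseline"] -
                 lab$value[lab$side == "right" & lab$timepoint == "baseline"])
  d_post <- mean(lab$value[lab$side == "left" & lab$timepoint == "wk3"] -
                 lab$value[lab$side == "right" & lab$timepoint == "wk3"])
  expect_lt(abs(d_base), 0.1)
  expect_equal(d_post, 2.3, tolerance = 0.1)
})
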