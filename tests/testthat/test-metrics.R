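test_that("the asymmetry index matches hand-computed cases and errors on bad input", {
  expect_equal(asymmetry_index(0.5, 0.5), 0)
  expect_equal(asymmetry_index(0.6, 0.4), 0.2)
  expect_equal(asymmetry_index(0.75, 0.25), 0.5)
  # limb-order invariance
  expect_equal(asymmetry_index(0.4, 0.6), asymmetry_index(0.6, 0.4))
  expect_error(asymmetry_index(0, 0.5), "positive")
  expect_error(asymmetry_index(0.5, -1), "positive")
})

test_that("knee flexion angle reproduces the straight and orthogonal cases", {
  expect_equal(knee_flexion_angle(c(0, 0, 1), c(0, 0, 0.5), c(0, 0, 0)), 0)
  expect_equal(knee_flexion_angle(c(0, 0, 0.5), c(0, 0, 0), c(0.5, 0, 0)), 90)
})

test_that("trailing limb angle reproduces the hand trigonometry case", {
  n <- 10
  tr <- trial_from_series(list(
    "greater_trochanter.right" = const_series(n, 0, -0.1, 0.9),
    "fifth_metatarsal.right" = const_series(n, -0.3, -0.1, 0)
  ))
  st <- manual_strides("right", fs = c(1, 5), to = c(3, 7), next_fs = c(5, 9))
  expect_equal(trailing_limb_angle(tr, st, "right"),
               atan2(0.3, 0.9) * 180 / pi, tolerance = 1e-9)
  # vertical limb: angle 0
  tr0 <- trial_from_series(list(
    "greater_trochanter.right" = const_series(n, 0, -0.1, 0.9),
    "fifth_metatarsal.right" = const_series(n, 0, -0.1, 0)
  ))
  expect_equal(trailing_limb_angle(tr0, st, "right"), 0)
})

test_that("hip hiking reproduces the hand trigonometry case and the level-pelvis zero", {
  n <- 30
  zl <- rep(1, n); zl[c(10, 24)] <- 1.02  # left crest raised at swing peaks
  tr <- trial_from_series(list(
    "iliac_crest.left" = cbind(0, 0.15, zl),
    "iliac_crest.right" = cbind(0, -0.15, rep(1, n))
  ))
  st <- manual_strides("left", fs = c(1, 15), to = c(7, 21), next_fs = c(15, 29))
  expect_equal(hip_hiking(tr, st, "left"), atan2(0.02, 0.30) * 180 / pi,
               tolerance = 1e-9)
  level <- trial_from_series(list(
    "iliac_crest.left" = const_series(n, 0, 0.15, 1),
    "iliac_crest.right" = const_series(n, 0, -0.15, 1)
  ))
  expect_equal(hip_hiking(level, st, "left"), 0)
})

test_that("circumduction reproduces the stance-reference subtraction and planar zero", {
  n <- 30
  y <- rep(0.10, n); y[c(10, 24)] <- 0.145
  tr <- trial_from_series(list("lateral_malleolus.left" = cbind(0, y, 0.08)))
  st <- manual_strides("left", fs = c(1, 15), to = c(7, 21), next_fs = c(15, 29))
  expect_equal(circumduction(tr, st, "left"), 0.045, tolerance = 1e-12)
  flat <- trial_from_series(list("lateral_malleolus.left" = const_series(n, 0, 0.10, 0.08)))
  expect_equal(circumduction(flat, st, "left"), 0)
  # displacement toward the midline floors at zero
  y2 <- rep(0.10, n); y2[c(10, 24)] <- 0.04
  toward <- trial_from_series(list("lateral_malleolus.left" = cbind(0, y2, 0.08)))
  expect_equal(circumduction(toward, st, "left"), 0)
})

test_that("step lengths follow the leading-minus-trailing malleolus convention", {
  n <- 10
  tr <- trial_from_series(list(
    "lateral_malleolus.left" = const_series(n, 0.30, 0.1, 0.08),
    "lateral_malleolus.right" = const_series(n, -0.25, -0.1, 0.08)
  ))
  st <- dplyr::bind_rows(
    manual_strides("left", fs = c(1, 5), to = c(3, 7), next_fs = c(5, 9)),
    manual_strides("right", fs = c(2, 6), to = c(4, 8), next_fs = c(6, 10))
  )
  sl <- step_lengths(tr, st)
  expect_equal(unique(sl$step_length[sl$side == "left"]), 0.55)
  expect_true(all(sl$step_to[sl$side == "right"]))  # right behind left: step-to
  expect_equal(unique(sl$step_length[sl$side == "right"]), 0.55)
})

test_that("simulator oracle: all seven metrics recover their ground truth", {
  out <- generate_trial(asym_params(), paretic_side = "right", group = "stroke")
  rec <- compute_gait_metrics(out$trial, filter_cutoff = NULL)
  tru <- out$truth$metrics
  expect_equal(rec$sla, tru$sla, tolerance = 0.01)
  expect_equal(rec$dlsta, tru$dlsta, tolerance = 0.01)
  expect_equal(rec$slsta, tru$slsta, tolerance = 0.01)
  expect_equal(rec$knee_flex_deg, tru$knee_flex_deg, tolerance = 0.5)
  expect_equal(rec$tla_deg, tru$tla_deg, tolerance = 1)
  expect_equal(rec$circumduction_m, tru$circumduction_m, tolerance = 0.005)
  expect_equal(rec$hip_hike_deg, tru$hip_hike_deg, tolerance = 1)
  expect_gte(rec$n_strides, 25)
})

test_that("temporal asymmetries match a hand-built asymmetric timeline", {
  # stance fractions 0.70 (paretic, right) and 0.62 (non-paretic), stride 1 s:
  # leading double supports are (f_contra - 0.5) T, single supports (1 - f_contra) T
  st <- dplyr::bind_rows(
    manual_strides("right", fs = c(1, 101), to = c(71, 171), next_fs = c(101, 201)),
    manual_strides("left", fs = c(51, 151), to = c(113, 213), next_fs = c(151, 251))
  )
  st$double_support[st$side == "right"] <- 0.12
  st$single_support[st$side == "right"] <- 0.38
  st$double_support[st$side == "left"] <- 0.20
  st$single_support[st$side == "left"] <- 0.30
  ta <- temporal_asymmetries(st, paretic_side = "right")
  expect_equal(ta$dlsta, abs(0.12 - 0.20) / (0.12 + 0.20))
  expect_equal(ta$slsta, abs(0.38 - 0.30) / (0.38 + 0.30))
})

test_that("angle metrics are scale-invariant and length metrics scale linearly", {
  out <- generate_trial(asym_params(n_strides = 10), paretic_side = "right",
                        group = "stroke")
  rec1 <- compute_gait_metrics(out$trial, filter_cutoff = NULL)
  big <- out$trial
  big$data$x <- big$data$x * 2.5
  big$data$y <- big$data$y * 2.5
  big$data$z <- big$data$z * 2.5
  rec2 <- compute_gait_metrics(big, filter_cutoff = NULL)
  expect_equal(rec2$knee_flex_deg, rec1$knee_flex_deg, tolerance = 1e-6)
  expect_equal(rec2$tla_deg, rec1$tla_deg, tolerance = 1e-6)
  expect_equal(rec2$hip_hike_deg, rec1$hip_hike_deg, tolerance = 1e-6)
  expect_equal(rec2$sla, rec1$sla, tolerance = 1e-6)  # ratio of lengths
  expect_equal(rec2$circumduction_m, 2.5 * rec1$circumduction_m, tolerance = 1e-9)
})

test_that("metric recovery degrades gracefully under marker noise with filtering", {
  set.seed(77)
  true_v <- c(); meas_v <- c()
  for (i in 1:12) {
    p <- random_params(n_strides = 20, noise_sd = 0.002)
    p$seed <- i
    out <- generate_trial(p, paretic_side = "right", group = "stroke")
    rec <- compute_gait_metrics(out$trial)  # default 6 Hz filtering
    true_v <- rbind(true_v, metrics_of(out$truth$metrics))
    meas_v <- rbind(meas_v, metrics_of(rec))
  }
  for (j in c("knee_flex_deg", "tla_deg", "circumduction_m")) {
    r2 <- stats::cor(true_v[, j], meas_v[, j])^2
    expect_gt(r2, 0.9)
  }
})

test_that("identical periodic data give identical records over different bins", {
  p <- asym_params(n_strides = 40)
  out <- generate_trial(p, paretic_side = "right", group = "stroke")
  rec_mid <- compute_gait_metrics(out$trial, bin_mode = "middle", bin_seconds = 15,
                                  filter_cutoff = NULL)
  rec_fin <- compute_gait_metrics(out$trial, bin_mode = "final", bin_seconds = 15,
                                  filter_cutoff = NULL)
  expect_equal(metrics_of(rec_mid), metrics_of(rec_fin), tolerance = 5e-3)
})

test_that("the inclusion filter applies the strict speed bound and calibration flag", {
  meta <- tibble::tibble(
    participant_id = c("A", "B", "C", "D"),
    speeds = list(c(0.21, 0.26, 0.31, 0.56), c(0.20, 0.5, 0.8),
                  c(0.5, 0.9), c(0.6, 1.0)),
    standing_calibration = c(TRUE, TRUE, FALSE, TRUE)
  )
  out <- apply_inclusion_filter(meta)
  expect_equal(out$included, c(TRUE, FALSE, FALSE, TRUE))
  expect_match(out$exclusion_reason[2], "slowest")
  expect_match(out$exclusion_reason[3], "calibration")
})
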