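test_that("speed centering matches arithmetic, is idempotent, and errors on constants", {
  d <- tibble::tibble(speed = c(0.5, 1.0, 1.5))
  out <- center_speed(d)
  expect_equal(out$speed_c, c(-0.5, 0, 0.5))
  expect_equal(attr(out, "speed_grand_mean"), 1.0)
  again <- center_speed(dplyr::mutate(out, speed = speed_c))
  expect_equal(again$speed_c, out$speed_c)
  expect_error(center_speed(tibble::tibble(speed = rep(1, 4))), "distinct")
})

test_that("coefficients are recovered exactly from noise-free model data", {
  beta <- c(0.1, 0.08, -0.08, -0.05)
  d <- simulate_metric_observations(30, 4, beta = beta, sigma_b = 0, sigma_e = 0,
                                    seed = 2)
  f <- suppressWarnings(suppressMessages(
    fit_metric_model(d, "value", estimator = "classical")))
  expect_equal(f$coefficients$estimate, beta, tolerance = 1e-6,
               ignore_attr = TRUE)
})

test_that("the robust fit reduces to the classical fit as tuning goes to infinity", {
  d <- simulate_metric_observations(40, 4, sigma_b = 0.04, sigma_e = 0.04, seed = 3)
  fc <- fit_metric_model(d, "value", "classical")
  for (psi in c("bisquare", "huber")) {
    fr <- fit_metric_model(d, "value", "robust", psi = psi, tuning = Inf)
    expect_lt(max(abs(fc$coefficients$estimate - fr$coefficients$estimate)), 1e-6)
  }
})

test_that("robust and classical fits agree on clean Gaussian data", {
  d <- simulate_metric_observations(50, 4, sigma_b = 0.04, sigma_e = 0.04, seed = 9)
  fc <- fit_metric_model(d, "value", "classical")
  fr <- fit_metric_model(d, "value", "robust")
  expect_lt(max(abs(fc$coefficients$estimate - fr$coefficients$estimate) /
                  fc$coefficients$std_error), 0.5)
  expect_true(fr$converged)
  expect_true(all(fr$coefficients$std_error > 0))
  expect_true(all(fr$coefficients$df > 0))
})

test_that("centering invariance: the group contrast matches the uncentred fit at the mean speed", {
  d <- simulate_metric_observations(30, 4, sigma_b = 0.03, sigma_e = 0.05, seed = 4)
  f <- fit_metric_model(d, "value", "classical")
  # uncentred fit via lme4 directly
  d2 <- d
  d2$g <- as.numeric(d2$group == "stroke")
  un <- lme4::lmer(value ~ g * speed + (1 | participant_id), data = d2, REML = TRUE)
  bu <- lme4::fixef(un)
  gm <- mean(d$speed)
  expect_equal(unname(f$coefficients$estimate[2]), unname(bu["g"] + bu["g:speed"] * gm),
               tolerance = 1e-8)
})

test_that("a gross outlier barely displaces the robust fit", {
  set.seed(11)
  ratios <- vapply(1:6, function(s) {
    d0 <- simulate_metric_observations(40, 4, sigma_b = 0.04, sigma_e = 0.04,
                                       seed = 50 + s)
    i <- sample(nrow(d0), 1)
    dx <- d0
    dx$value[i] <- dx$value[i] + 10 * 0.04
    c0 <- fit_metric_model(d0, "value", "classical")$coefficients$estimate
    c1 <- fit_metric_model(dx, "value", "classical")$coefficients$estimate
    r0 <- fit_metric_model(d0, "value", "robust")$coefficients$estimate
    r1 <- fit_metric_model(dx, "value", "robust")$coefficients$estimate
    sqrt(sum((r1 - r0)^2)) / sqrt(sum((c1 - c0)^2))
  }, numeric(1))
  expect_lt(mean(ratios), 0.2)
})

test_that("a singular random intercept falls back to a fixed-effects robust fit", {
  d <- simulate_metric_observations(20, 4, sigma_b = 0, sigma_e = 0.05, seed = 8)
  suppressMessages(expect_warning(f <- fit_metric_model(d, "value", "robust"),
                                  "singular"))
  expect_true(f$singular)
  expect_true(all(is.finite(f$coefficients$std_error)))
})

test_that("fit_all_metrics drops missing rows listwise per metric", {
  coh <- cohort_metrics(generate_cohort(c(stroke = 6, neurotypical = 6), seed = 8))
  coh$hip_hike_deg[coh$participant_id %in% c("S01", "N01")] <- NA
  fits <- suppressWarnings(fit_all_metrics(coh, estimator = "classical"))
  expect_length(fits, 7)
  expect_equal(fits$hip_hike_deg$n_participants, fits$sla$n_participants - 2)
  td <- tidy_metric_fits(fits)
  expect_equal(nrow(td), 28)
  # skipping sparse metrics
  coh$tla_deg[-(1:5)] <- NA
  suppressWarnings(expect_warning(
    fit_all_metrics(coh, metrics = "tla_deg", estimator = "classical"),
    "skipping"))
})

test_that("group coefficient signs track the generator's construction", {
  coh <- cohort_metrics(generate_cohort(c(stroke = 10, neurotypical = 10),
                                        profiles = contrast_profiles(), seed = 12))
  fits <- suppressWarnings(fit_all_metrics(coh, estimator = "classical"))
  signs <- vapply(fits, function(f) sign(f$coefficients$estimate[2]), numeric(1))
  # stroke-coded-1: larger asymmetries, hiking, circumduction; smaller knee
  # flexion and trailing limb angle
  expect_equal(unname(signs[c("sla", "dlsta", "slsta", "hip_hike_deg",
                              "circumduction_m")]), rep(1, 5))
  expect_equal(unname(signs[c("knee_flex_deg", "tla_deg")]), rep(-1, 2))
})

test_that("tidy and glance return the documented shapes", {
  d <- simulate_metric_observations(20, 3, sigma_b = 0.03, sigma_e = 0.04, seed = 5)
  f <- fit_metric_model(d, "value", "robust")
  td <- tidy(f)
  expect_equal(names(td), c("metric", "term", "estimate", "std_error", "df", "p_value"))
  expect_equal(td$term, c("(Intercept)", "group", "speed", "group:speed"))
  gl <- glance(f)
  expect_equal(gl$n_obs, 60)
  expect_equal(gl$estimator, "robust")
})
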