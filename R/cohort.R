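#' Group-level parameter profiles for cohort simulation
#'
#' Returns the distribution (mean, sd and linear speed slope) of every
#' participant-level gait parameter for a simulated group. The
#' `"neurotypical"` profile emulates symmetric treadmill gait of older
#' adults; the `"stroke"` profile emulates hemiparetic gait: larger
#' spatiotemporal asymmetries, reduced paretic knee flexion and trailing
#' limb angle, and larger hip hiking and circumduction, with weaker
#' speed-dependent increases in paretic knee flexion. Speed slopes are
#' expressed per m/s of deviation from the participant's self-selected
#' speed.
#'
#' @param group `"neurotypical"` or `"stroke"`.
#' @param effect_scale Multiplier on the group's mean deviation from the
#'   neurotypical means (1 = default profile). Values > 1 build cohorts
#'   with stronger group contrast for separability studies.
#' @param sd_scale Multiplier on all between-participant standard
#'   deviations.
#' @return A list of parameter specifications, each a numeric vector with
#'   elements `mean`, `sd`, `slope`.
#' @export
group_profile <- function(group = c("neurotypical", "stroke"),
                          effect_scale = 1, sd_scale = 1) {
  group <- match.arg(group)
  spec <- function(m_nt, m_st, sd, slope_nt, slope_st = slope_nt) {
    if (group == "neurotypical") {
      c(mean = m_nt, sd = sd * sd_scale, slope = slope_nt)
    } else {
      c(mean = m_nt + (m_st - m_nt) * effect_scale, sd = sd * sd_scale,
        slope = slope_st)
    }
  }
  list(
    self_selected_speed = spec(1.15, 0.70, if (group == "stroke") 0.22 else 0.13, 0),
    stride_time = spec(1.08, 1.22, 0.08, -0.22),            # s, at self-selected speed
    step_length_asymmetry = spec(0.005, 0.085, if (group == "stroke") 0.055 else 0.018,
                                 -0.02, -0.055),            # paretic-minus-nonparetic, signed
    stance_fraction = spec(0.63, 0.645, 0.012, -0.035),     # mean of both limbs
    stance_imbalance = spec(0.003, 0.038, if (group == "stroke") 0.018 else 0.006,
                            -0.004, -0.012),                # nonparetic minus paretic
    knee_flexion_peak = spec(62, 45, if (group == "stroke") 7 else 4, 12, 4),  # deg
    tla_peak = spec(22, 14, 3.2, 4.5, 7.5),                 # deg
    hip_hike_amp = spec(1.6, 6.4, if (group == "stroke") 2.2 else 0.8,
                        0.6, 1.8),                          # deg
    circumduction_amp = spec(0.008, 0.028, if (group == "stroke") 0.011 else 0.004,
                             0.002, 0.006),                 # m
    noise_sd = spec(0.002, 0.002, 0, 0),
    group = group
  )
}

draw_spec <- function(spec) stats::rnorm(1, spec[["mean"]], spec[["sd"]])

clip <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# participant-level latent draws shared across that participant's speeds
draw_participant <- function(profile) {
  ss <- clip(draw_spec(profile$self_selected_speed), 0.25, 1.6)
  list(
    self_selected_speed = ss,
    stride_time = clip(draw_spec(profile$stride_time), 0.85, 2.1),
    step_length_asymmetry = clip(draw_spec(profile$step_length_asymmetry), -0.4, 0.5),
    stance_fraction = clip(draw_spec(profile$stance_fraction), 0.56, 0.72),
    stance_imbalance = clip(draw_spec(profile$stance_imbalance), -0.08, 0.12),
    knee_flexion_peak = clip(draw_spec(profile$knee_flexion_peak), 14, 85),
    tla_peak = clip(draw_spec(profile$tla_peak), 3, 33),
    hip_hike_amp = clip(draw_spec(profile$hip_hike_amp), 0, 12),
    circumduction_amp = clip(draw_spec(profile$circumduction_amp), 0, 0.08),
    noise_sd = max(profile$noise_sd[["mean"]], 0)
  )
}

# evaluate a participant's parameters at one belt speed and return gait_params
participant_params_at_speed <- function(draw, profile, speed, paretic_side,
                                        sampling_rate = 100, n_strides = 25) {
  dv <- speed - draw$self_selected_speed
  at <- function(name, lo, hi) {
    clip(draw[[name]] + profile[[name]][["slope"]] * dv, lo, hi)
  }
  stride_time <- at("stride_time", 0.8, 2.2)
  sla <- at("step_length_asymmetry", -0.45, 0.55)
  f_mean <- at("stance_fraction", 0.55, 0.74)
  imb <- at("stance_imbalance", -0.1, 0.15)
  f_par <- clip(f_mean - imb / 2, 0.52, 0.88)
  f_non <- clip(f_mean + imb / 2, 0.52, 0.88)
  knee_par <- at("knee_flexion_peak", 12, 95)
  tla_par <- at("tla_peak", 2, 35)
  hike_par <- at("hip_hike_amp", 0, 14)
  circ_par <- at("circumduction_amp", 0, 0.09)
  # the non-paretic limb stays close to the neurotypical pattern
  nt <- group_profile("neurotypical")
  knee_non <- clip(nt$knee_flexion_peak[["mean"]] + nt$knee_flexion_peak[["slope"]] * dv, 12, 95)
  tla_non <- clip(nt$tla_peak[["mean"]] + nt$tla_peak[["slope"]] * dv, 2, 35)
  hike_non <- clip(nt$hip_hike_amp[["mean"]], 0, 14)
  circ_non <- clip(nt$circumduction_amp[["mean"]], 0, 0.09)
  ps <- if (paretic_side %in% c("left", "right")) paretic_side else "right"
  pick <- function(par_val, non_val, side) if (side == ps) par_val else non_val
  args <- list(
    stride_time = stride_time, belt_speed = speed,
    step_length_asymmetry = if (ps == "left") sla else -sla,
    sampling_rate = sampling_rate, noise_sd = draw$noise_sd,
    n_strides = n_strides
  )
  for (side in c("left", "right")) {
    args[[paste0("stance_fraction_", side)]] <- pick(f_par, f_non, side)
    args[[paste0("knee_flexion_peak_", side)]] <- pick(knee_par, knee_non, side)
    args[[paste0("tla_peak_", side)]] <- pick(tla_par, tla_non, side)
    args[[paste0("hip_hike_amp_", side)]] <- pick(hike_par, hike_non, side)
    args[[paste0("circumduction_amp_", side)]] <- pick(circ_par, circ_non, side)
  }
  do.call(gait_params, args)
}

# latent impairment summary used to attach a correlated Fugl-Meyer score
impairment_score <- function(draw) {
  nt <- group_profile("neurotypical")
  dev <- c(
    (abs(draw$step_length_asymmetry) - abs(nt$step_length_asymmetry[["mean"]])) / 0.06,
    (abs(draw$stance_imbalance) - abs(nt$stance_imbalance[["mean"]])) / 0.03,
    (nt$knee_flexion_peak[["mean"]] - draw$knee_flexion_peak) / 14,
    (nt$tla_peak[["mean"]] - draw$tla_peak) / 7,
    (draw$hip_hike_amp - nt$hip_hike_amp[["mean"]]) / 4,
    (draw$circumduction_amp - nt$circumduction_amp[["mean"]]) / 0.018
  )
  mean(dev)
}

#' Generate a synthetic two-group cohort
#'
#' Draws participant-level gait parameters from group profiles, evaluates
#' them at a ladder of belt speeds per participant (80%, 100% and 120% of
#' self-selected speed plus a fastest speed), attaches a synthetic
#' Lower-Extremity Fugl-Meyer score anticorrelated with the latent
#' impairment of stroke participants, and returns the ground-truth metric
#' values (and optionally full marker trials) for every participant-speed
#' observation.
#'
#' Each participant is simulated from an independent random substream
#' derived from `seed`, so dropping a participant does not perturb the
#' others and the same seed reproduces the cohort exactly.
#'
#' @param n_per_group Named integer vector, e.g.
#'   `c(stroke = 28, neurotypical = 26)`, or a single integer used for both
#'   groups.
#' @param profiles Named list with elements `stroke` and `neurotypical`,
#'   each from [group_profile()].
#' @param speed_factors Multiples of self-selected speed defining the
#'   per-participant speed ladder; the last entry is the "fast" condition.
#' @param trajectories If `TRUE`, generate full marker trials (list column
#'   `trial_data`); otherwise only parameters and ground-truth metrics.
#' @param sampling_rate,n_strides Passed to the per-trial generator.
#' @param seed Integer seed; required for reproducibility.
#' @return A tibble, one row per participant-speed observation: metadata
#'   (`participant_id`, `group`, `paretic_side`, `age`, `le_fugl_meyer`),
#'   `speed_condition`, `speed`, the seven ground-truth metrics, a `params`
#'   list column, and when `trajectories = TRUE` a `trial_data` list column
#'   holding `list(trial, truth)` per observation.
#' @export
generate_cohort <- function(n_per_group = c(stroke = 14, neurotypical = 13),
                            profiles = list(stroke = group_profile("stroke"),
                                            neurotypical = group_profile("neurotypical")),
                            speed_factors = c(s80 = 0.8, self_selected = 1.0,
                                              s120 = 1.2, fast = 1.45),
                            trajectories = FALSE,
                            sampling_rate = 100, n_strides = 25,
                            seed = 1) {
  if (length(n_per_group) == 1 && is.null(names(n_per_group))) {
    n_per_group <- c(stroke = n_per_group, neurotypical = n_per_group)
  }
  if (any(n_per_group < 1)) stop("n_per_group must be >= 1 for every group")
  for (g in names(profiles)) {
    sds <- vapply(profiles[[g]][setdiff(names(profiles[[g]]), "group")],
                  function(s) s[["sd"]], numeric(1))
    if (any(sds < 0)) stop("degenerate profile: negative sd in group ", g)
  }
  stopifnot(is.numeric(seed), length(seed) == 1)

  rows <- list()
  idx <- 0
  for (grp in names(n_per_group)) {
    profile <- profiles[[grp]]
    for (i in seq_len(n_per_group[[grp]])) {
      idx <- idx + 1
      set.seed(as.integer(((as.numeric(seed) %% 1000003) * 1009 + 7919 * idx) %% 2147483647))
      draw <- draw_participant(profile)
      paretic <- if (grp == "stroke") sample(c("left", "right"), 1) else "none"
      age <- round(clip(stats::rnorm(1, if (grp == "stroke") 62 else 67, 9), 40, 85))
      fm <- NA_integer_
      if (grp == "stroke") {
        fm <- as.integer(clip(round(33 - 7 * impairment_score(draw) +
                                      stats::rnorm(1, 0, 2)), 0, 34))
      }
      pid <- sprintf("%s%02d", if (grp == "stroke") "S" else "N", i)
      speeds <- clip(draw$self_selected_speed * speed_factors, 0.2, 2.0)
      cond_names <- names(speed_factors)
      if (is.null(cond_names)) cond_names <- paste0("v", seq_along(speed_factors))
      for (j in seq_along(speeds)) {
        prm <- participant_params_at_speed(draw, profile, speeds[[j]], paretic,
                                           sampling_rate, n_strides)
        truth_m <- ground_truth_metrics(prm, paretic)
        row <- tibble::tibble(
          participant_id = pid, group = grp, paretic_side = paretic,
          age = age, le_fugl_meyer = fm,
          speed_condition = cond_names[j],
          speed = speeds[[j]]
        )
        row <- dplyr::bind_cols(row, truth_m)
        row$params <- list(prm)
        if (trajectories) {
          row$trial_data <- list(generate_trial(
            prm, participant_id = pid, group = grp,
            paretic_side = if (paretic == "none") "none" else paretic
          ))
        }
        rows[[length(rows) + 1]] <- row
      }
    }
  }
  dplyr::bind_rows(rows)
}

#' Extract the ground-truth metrics table from a cohort
#'
#' Convenience accessor returning the columns the statistical and clustering
#' modules consume: metadata, speed and the seven metric values.
#'
#' @param cohort Output of [generate_cohort()].
#' @return A tibble.
#' @export
cohort_metrics <- function(cohort) {
  dplyr::select(cohort, "participant_id", "group", "paretic_side", "age",
                "le_fugl_meyer", "speed_condition", "speed",
                dplyr::all_of(METRIC_COLUMNS))
}

#' Names of the seven gait metric columns
#' @format Character vector of length 7.
#' @export
METRIC_COLUMNS <- c("sla", "dlsta", "slsta", "knee_flex_deg", "tla_deg",
                    "circumduction_m", "hip_hike_deg")
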