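# shared fixtures built in code

# an asymmetric hemiparetic-like parameter set with exactly-known truths;
# stride time chosen so stride boundaries do not align with the sample grid
asym_params <- function(n_strides = 30, noise_sd = 0, sampling_rate = 100) {
  gait_params(
    stride_time = 1.1037, belt_speed = 1.0,
    stance_fraction_left = 0.60, stance_fraction_right = 0.65,
    step_length_asymmetry = -0.2,
    knee_flexion_peak_right = 60, knee_flexion_peak_left = 45,
    tla_peak_right = 15, tla_peak_left = 20,
    circumduction_amp_right = 0.03, circumduction_amp_left = 0.008,
    hip_hike_amp_right = 6, hip_hike_amp_left = 1,
    n_strides = n_strides, noise_sd = noise_sd, sampling_rate = sampling_rate
  )
}

# random physiological parameter draw used by sweep-style tests; cadence
# rises with belt speed so the stance excursion stays reachable
random_params <- function(n_strides = 30, noise_sd = 0) {
  v <- stats::runif(1, 0.3, 1.4)
  gait_params(
    stride_time = stats::runif(1, 0.95, 1.3) - 0.35 * max(v - 0.8, 0) + 0.0037,
    belt_speed = v,
    stance_fraction_left = stats::runif(1, 0.57, 0.65),
    stance_fraction_right = stats::runif(1, 0.60, 0.68),
    step_length_asymmetry = stats::runif(1, -0.3, 0.05),
    knee_flexion_peak_right = stats::runif(1, 25, 72),
    knee_flexion_peak_left = stats::runif(1, 40, 65),
    tla_peak_right = stats::runif(1, 6, 26),
    tla_peak_left = stats::runif(1, 12, 24),
    circumduction_amp_right = stats::runif(1, 0, 0.05),
    circumduction_amp_left = stats::runif(1, 0, 0.01),
    hip_hike_amp_right = stats::runif(1, 0, 9),
    hip_hike_amp_left = stats::runif(1, 0, 2),
    n_strides = n_strides, noise_sd = noise_sd
  )
}

# minimal single/multi-marker trial from explicit coordinate matrices
trial_from_series <- function(series, sampling_rate = 100, participant_id = "T1",
                              group = "neurotypical", paretic_side = "none",
                              belt_speed = 1) {
  data <- purrr::map_dfr(names(series), function(key) {
    parts <- strsplit(key, ".", fixed = TRUE)[[1]]
    m <- series[[key]]
    n <- nrow(m)
    tibble::tibble(frame = seq_len(n), time_s = (seq_len(n) - 1) / sampling_rate,
                   marker = parts[1], side = parts[2],
                   x = m[, 1], y = m[, 2], z = m[, 3])
  })
  marker_trial(data, participant_id, group, paretic_side, belt_speed, sampling_rate)
}

const_series <- function(n, x, y, z) cbind(x = rep(x, n), y = rep(y, n), z = rep(z, n))

# a stride table for hand-built marker configurations (all unflagged)
manual_strides <- function(side, fs, to, next_fs, contra_fs = NA_integer_,
                           contra_to = NA_integer_, sampling_rate = 100) {
  tibble::tibble(
    side = side, stride = seq_along(fs),
    fs_frame = as.integer(fs), to_frame = as.integer(to),
    next_fs_frame = as.integer(next_fs),
    contra_fs_frame = as.integer(contra_fs), contra_to_frame = as.integer(contra_to),
    stride_time = (next_fs - fs) / sampling_rate,
    stance_time = (to - fs) / sampling_rate,
    swing_time = (next_fs - to) / sampling_rate,
    double_support = NA_real_, single_support = NA_real_,
    flagged = FALSE, flag_reason = NA_character_
  )
}

# profile pair whose impairment gap widens with speed, for the
# cluster-distance-by-condition checks
speed_widening_profiles <- function() {
  st <- group_profile("stroke", effect_scale = 0.9, sd_scale = 0.8)
  nt <- group_profile("neurotypical", sd_scale = 0.8)
  st$knee_flexion_peak["slope"] <- 0;        nt$knee_flexion_peak["slope"] <- 14
  st$hip_hike_amp["slope"] <- 2.5;           nt$hip_hike_amp["slope"] <- 0.2
  st$circumduction_amp["slope"] <- 0.015;    nt$circumduction_amp["slope"] <- 0
  st$step_length_asymmetry["slope"] <- 0.05; nt$step_length_asymmetry["slope"] <- -0.005
  st$stance_imbalance["slope"] <- 0.025;     nt$stance_imbalance["slope"] <- 0
  st$tla_peak["slope"] <- 0;                 nt$tla_peak["slope"] <- 6
  list(stroke = st, neurotypical = nt)
}

# strongly separated profile pair for recovery checks
contrast_profiles <- function() {
  list(stroke = group_profile("stroke", effect_scale = 1.6, sd_scale = 0.7),
       neurotypical = group_profile("neurotypical", sd_scale = 0.7))
}

metrics_of <- function(rec) {
  unlist(rec[, c("sla", "dlsta", "slsta", "knee_flex_deg", "tla_deg",
                 "circumduction_m", "hip_hike_deg")])
}
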