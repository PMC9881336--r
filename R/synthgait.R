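#' Parameters of the synthetic treadmill gait model
#'
#' Defines one participant-speed trial of the generative gait model. The
#' model hangs a planar three-segment limb (pelvis/hip, thigh, shank) from a
#' stationary pelvis and prescribes the lateral-malleolus trajectory
#' analytically: during stance the malleolus translates rearward at the belt
#' speed; during swing its fore-aft velocity follows a half-sinusoid, so
#' foot strike and toe off are provably the most anterior and posterior
#' trajectory points and their times are known in closed form. Knee flexion,
#' trailing limb angle, hip hiking and circumduction are injected so that
#' each metric's ground-truth value equals the corresponding parameter.
#'
#' On a treadmill at steady state the two step lengths must sum to
#' `belt_speed * stride_time` (the belt carries the body one stride length
#' rearward per stride). Either supply both step lengths satisfying that
#' constraint, or supply `step_length_asymmetry` (signed,
#' `(left - right) / (left + right)`) and let the constructor derive them.
#'
#' @param stride_time Stride period in seconds.
#' @param belt_speed Belt speed in m/s.
#' @param stance_fraction_left,stance_fraction_right Fraction of the stride
#'   spent in stance, in (0.5, 0.9).
#' @param step_length_left,step_length_right Step lengths in metres, or
#'   `NULL` to derive from `step_length_asymmetry`.
#' @param step_length_asymmetry Signed step-length asymmetry used when step
#'   lengths are not given.
#' @param knee_flexion_peak_left,knee_flexion_peak_right Peak swing knee
#'   flexion in degrees (0 = straight leg); must exceed 10 degrees so the
#'   swing knee clears the near-straight stance configuration.
#' @param hip_hike_amp_left,hip_hike_amp_right Peak swing-phase pelvic
#'   obliquity (swing-side crest up) in degrees.
#' @param circumduction_amp_left,circumduction_amp_right Peak lateral
#'   malleolus excursion during swing, metres.
#' @param tla_peak_left,tla_peak_right Trailing limb angle at toe off,
#'   degrees from vertical (positive = foot posterior to hip).
#' @param thigh_length,shank_length,foot_length,pelvis_width Segment
#'   dimensions in metres.
#' @param sampling_rate Sampling rate in Hz (>= 50).
#' @param noise_sd Gaussian marker noise standard deviation in metres,
#'   applied independently per axis and frame.
#' @param n_strides Number of strides to simulate (>= 2).
#' @param seed Optional integer seed used by [generate_trial()] for the
#'   marker noise.
#' @return A validated list of class `gait_params`.
#' @export
gait_params <- function(stride_time = 1.1037,
                        belt_speed = 1.0,
                        stance_fraction_left = 0.62,
                        stance_fraction_right = 0.62,
                        step_length_left = NULL,
                        step_length_right = NULL,
                        step_length_asymmetry = 0,
                        knee_flexion_peak_left = 60,
                        knee_flexion_peak_right = 60,
                        hip_hike_amp_left = 1.5,
                        hip_hike_amp_right = 1.5,
                        circumduction_amp_left = 0.008,
                        circumduction_amp_right = 0.008,
                        tla_peak_left = 18,
                        tla_peak_right = 18,
                        thigh_length = 0.41,
                        shank_length = 0.43,
                        foot_length = 0.25,
                        pelvis_width = 0.28,
                        sampling_rate = 100,
                        noise_sd = 0,
                        n_strides = 25,
                        seed = NULL) {
  stride_length <- belt_speed * stride_time
  if (is.null(step_length_left) || is.null(step_length_right)) {
    a <- step_length_asymmetry
    if (abs(a) >= 1) stop("step_length_asymmetry must lie in (-1, 1)")
    step_length_left <- stride_length * (1 + a) / 2
    step_length_right <- stride_length * (1 - a) / 2
  }
  p <- list(
    stride_time = stride_time, belt_speed = belt_speed,
    stance_fraction_left = stance_fraction_left,
    stance_fraction_right = stance_fraction_right,
    step_length_left = step_length_left,
    step_length_right = step_length_right,
    knee_flexion_peak_left = knee_flexion_peak_left,
    knee_flexion_peak_right = knee_flexion_peak_right,
    hip_hike_amp_left = hip_hike_amp_left,
    hip_hike_amp_right = hip_hike_amp_right,
    circumduction_amp_left = circumduction_amp_left,
    circumduction_amp_right = circumduction_amp_right,
    tla_peak_left = tla_peak_left, tla_peak_right = tla_peak_right,
    thigh_length = thigh_length, shank_length = shank_length,
    foot_length = foot_length, pelvis_width = pelvis_width,
    sampling_rate = sampling_rate, noise_sd = noise_sd,
    n_strides = as.integer(n_strides), seed = seed
  )
  validate_gait_params(p)
  structure(p, class = "gait_params")
}

validate_gait_params <- function(p) {
  chk <- function(ok, msg) if (!isTRUE(ok)) stop("invalid gait_params: ", msg, call. = FALSE)
  chk(p$stride_time > 0, "stride_time must be > 0")
  chk(p$belt_speed > 0, "belt_speed must be > 0")
  for (s in c("left", "right")) {
    f <- p[[paste0("stance_fraction_", s)]]
    chk(f > 0.5 && f < 0.9, sprintf("stance_fraction_%s must lie in (0.5, 0.9)", s))
    k <- p[[paste0("knee_flexion_peak_", s)]]
    chk(k >= 10 && k < 120, sprintf("knee_flexion_peak_%s must lie in [10, 120) deg", s))
    chk(p[[paste0("hip_hike_amp_", s)]] >= 0, "hip hike amplitudes must be >= 0")
    chk(p[[paste0("circumduction_amp_", s)]] >= 0, "circumduction amplitudes must be >= 0")
    tla <- p[[paste0("tla_peak_", s)]]
    chk(tla >= 0 && tla < 40, sprintf("tla_peak_%s must lie in [0, 40) deg", s))
  }
  for (nm in c("thigh_length", "shank_length", "foot_length", "pelvis_width")) {
    chk(p[[nm]] > 0, paste(nm, "must be > 0"))
  }
  chk(p$noise_sd >= 0, "noise_sd must be >= 0")
  chk(p$sampling_rate >= 50, "sampling_rate must be >= 50 Hz")
  chk(p$n_strides >= 2, "n_strides must be >= 2")
  leg <- p$thigh_length + p$shank_length
  for (s in c("left", "right")) {
    sl <- p[[paste0("step_length_", s)]]
    chk(sl > 0, sprintf("step_length_%s must be > 0", s))
    if (sl > 1.5 * leg) {
      stop(sprintf(paste0(
        "non-physiological parameters: step_length_%s = %.2f m exceeds ",
        "1.5 x leg length (%.2f m)"), s, sl, 1.5 * leg), call. = FALSE)
    }
  }
  sl_sum <- p$step_length_left + p$step_length_right
  stride_length <- p$belt_speed * p$stride_time
  if (abs(sl_sum - stride_length) > 1e-6) {
    stop(sprintf(paste0(
      "inconsistent parameters: step lengths must sum to belt_speed * ",
      "stride_time on a treadmill at steady state (%.4f + %.4f != %.4f)"),
      p$step_length_left, p$step_length_right, stride_length), call. = FALSE)
  }
  invisible(p)
}

# distance between hip and ankle implied by a knee flexion angle (law of
# cosines; flexion 0 = straight leg)
knee_dist <- function(thigh, shank, flexion_deg) {
  sqrt(thigh^2 + shank^2 + 2 * thigh * shank * cos(flexion_deg * pi / 180))
}

ANKLE_HEIGHT <- 0.08      # stance-phase lateral malleolus marker height, m
STANCE_FLEXION <- 5       # near-straight stance knee flexion floor, deg
MT5_FORWARD <- 0.8        # fifth metatarsal fore-aft offset, fraction of foot
MT5_DROP <- 0.04          # fifth metatarsal height below the malleolus, m
CREST_RISE <- 0.18        # iliac crest height above the hip joint, m
PHASE <- c(right = 0.3, left = 0.8)  # foot-strike phase within the stride

# Per-limb geometric constants of the analytic trajectory model.
limb_geometry <- function(p, side) {
  f <- p[[paste0("stance_fraction_", side)]]
  T_ <- p$stride_time
  v <- p$belt_speed
  sl_l <- p$step_length_left
  sl_r <- p$step_length_right
  # anterior extreme offsets chosen so the step-length definition
  # (leading minus trailing malleolus at foot strike) returns the parameters
  a_off <- (sl_r - sl_l) / 4
  A <- if (side == "right") a_off else -a_off
  D <- v * f * T_
  P <- A - D
  d_cap <- knee_dist(p$thigh_length, p$shank_length, STANCE_FLEXION)
  d_peak <- knee_dist(p$thigh_length, p$shank_length,
                      p[[paste0("knee_flexion_peak_", side)]])
  z_hip <- ANKLE_HEIGHT + d_cap
  y_hip <- if (side == "left") p$pelvis_width / 2 else -p$pelvis_width / 2
  # hip fore-aft placement pinned so the trailing limb angle at toe off
  # equals the tla parameter; solved by fixed-point iteration
  tla <- p[[paste0("tla_peak_", side)]] * pi / 180
  x_hip <- P + MT5_FORWARD * p$foot_length + tan(tla) * d_cap * 0.9
  for (i in 1:60) {
    rad <- d_cap^2 - (P - x_hip)^2
    if (rad <= 0) {
      stop("non-physiological parameters: trailing limb angle too large for ",
           "the limb geometry", call. = FALSE)
    }
    x_new <- P + MT5_FORWARD * p$foot_length + tan(tla) * (sqrt(rad) + MT5_DROP)
    if (abs(x_new - x_hip) < 1e-12) { x_hip <- x_new; break }
    x_hip <- x_new
  }
  if (max(abs(c(A, P) - x_hip)) > 0.95 * d_cap) {
    stop("non-physiological parameters: stance excursion exceeds the limb ",
         "length", call. = FALSE)
  }
  list(
    side = side, f = f, T_ = T_, v = v, phase = PHASE[[side]],
    A = A, P = P, D = D, T_swing = (1 - f) * T_,
    d_cap = d_cap, d_peak = d_peak,
    z_hip = z_hip, y_hip = y_hip, x_hip = x_hip,
    circ = p[[paste0("circumduction_amp_", side)]],
    lat_sign = if (side == "left") 1 else -1,
    hike = p[[paste0("hip_hike_amp_", side)]]
  )
}

# stride phase in [0, 1) with 0 at foot strike
stride_phase <- function(t, g) ((t / g$T_) - g$phase) %% 1

# analytic ankle (lateral malleolus) trajectory; returns n x 3 matrix
ankle_trajectory <- function(t, g) {
  tau <- stride_phase(t, g)
  stance <- tau < g$f
  u <- pmax((tau - g$f) / (1 - g$f), 0)
  x <- ifelse(stance, g$A - g$v * tau * g$T_,
              g$P + g$D * (1 - cos(pi * u)) / 2)
  dy <- ifelse(stance, 0, g$lat_sign * g$circ * sin(pi * u))
  s2 <- sin(pi * u)^2
  d <- ifelse(stance, g$d_cap, (1 - s2) * g$d_cap + s2 * g$d_peak)
  dx <- x - g$x_hip
  rad <- d^2 - dx^2 - dy^2
  if (any(rad <= 0)) {
    stop("non-physiological parameters: swing trajectory leaves the ",
         "reachable workspace of the limb", call. = FALSE)
  }
  cbind(x = x, y = g$y_hip + dy, z = g$z_hip - sqrt(rad))
}

# swing-phase pelvic hike contribution of one limb (degrees, limb-side up)
hike_profile <- function(t, g) {
  tau <- stride_phase(t, g)
  u <- pmax((tau - g$f) / (1 - g$f), 0)
  ifelse(tau < g$f, 0, g$hike * sin(pi * u))
}

# two-link inverse kinematics: knee (lateral femoral epicondyle) position
# given hip and ankle, bending anteriorly; exact segment lengths in 3D
knee_from_hip_ankle <- function(hip, ankle, thigh, shank) {
  dvec <- ankle - matrix(hip, nrow(ankle), 3, byrow = TRUE)
  d <- sqrt(rowSums(dvec^2))
  a <- (thigh^2 + d^2 - shank^2) / (2 * d)
  h <- sqrt(pmax(thigh^2 - a^2, 0))
  u <- dvec / d
  # bend direction: anterior unit vector made orthogonal to the hip-ankle axis
  w <- cbind(1 - u[, 1]^2, -u[, 1] * u[, 2], -u[, 1] * u[, 3])
  wn <- sqrt(rowSums(w^2))
  w <- w / wn
  ctr <- matrix(hip, nrow(ankle), 3, byrow = TRUE) + a * u
  ctr + h * w
}

#' Generate one synthetic treadmill trial with exact ground truth
#'
#' Simulates bilateral trajectories of the five-marker lower-limb set for one
#' participant at one belt speed and records the exact gait-event times and
#' the seven metric values implied by the parameters, so that the event
#' detector and metric computations can be validated against a known answer.
#'
#' @param params A [gait_params()] object.
#' @param participant_id Identifier stored in the trial.
#' @param group `"neurotypical"` or `"stroke"`.
#' @param paretic_side `"none"`, `"left"` or `"right"`. Ground-truth metrics
#'   are reported for the paretic limb, or the right limb when `"none"`.
#' @param drop_markers Character vector of `"marker.side"` series to omit,
#'   e.g. `c("iliac_crest.left", "iliac_crest.right")`, emulating marker
#'   occlusion/dropout.
#' @return A list with elements `trial` (a [marker_trial()]) and `truth`
#'   (list with `params`, per-limb `events`, and a one-row `metrics` tibble).
#' @examples
#' out <- generate_trial(gait_params(n_strides = 5, seed = 1))
#' out$truth$metrics
#' @export
generate_trial <- function(params, participant_id = "synth01",
                           group = c("neurotypical", "stroke"),
                           paretic_side = c("none", "left", "right"),
                           drop_markers = character()) {
  stopifnot(inherits(params, "gait_params"))
  group <- match.arg(group)
  paretic_side <- match.arg(paretic_side)
  p <- params
  duration <- p$n_strides * p$stride_time
  n <- floor(duration * p$sampling_rate) + 1
  t <- (seq_len(n) - 1) / p$sampling_rate

  geom <- list(left = limb_geometry(p, "left"), right = limb_geometry(p, "right"))

  # pelvic obliquity (deg, left-side-up positive) from both swing profiles
  theta <- hike_profile(t, geom$left) - hike_profile(t, geom$right)
  x_pelvis <- mean(c(geom$left$x_hip, geom$right$x_hip))
  z_crest0 <- geom$left$z_hip + CREST_RISE
  half_w <- p$pelvis_width / 2

  series <- list()
  for (side in c("left", "right")) {
    g <- geom[[side]]
    lm <- ankle_trajectory(t, g)
    hip <- c(g$x_hip, g$y_hip, g$z_hip)
    gt <- matrix(hip, n, 3, byrow = TRUE)
    lfe <- knee_from_hip_ankle(hip, lm, p$thigh_length, p$shank_length)
    mt5 <- lm + matrix(c(MT5_FORWARD * p$foot_length, 0, -MT5_DROP),
                       n, 3, byrow = TRUE)
    sgn <- if (side == "left") 1 else -1
    ic <- cbind(x = rep(x_pelvis, n), y = rep(sgn * half_w, n),
                z = z_crest0 + sgn * half_w * tan(theta * pi / 180))
    series[[paste0("iliac_crest.", side)]] <- ic
    series[[paste0("greater_trochanter.", side)]] <- gt
    series[[paste0("lateral_femoral_epicondyle.", side)]] <- lfe
    series[[paste0("lateral_malleolus.", side)]] <- lm
    series[[paste0("fifth_metatarsal.", side)]] <- mt5
  }

  if (!is.null(p$seed)) set.seed(p$seed)
  if (p$noise_sd > 0) {
    series <- lapply(series, function(m) m + matrix(stats::rnorm(3 * n, 0, p$noise_sd), n, 3))
  }
  series <- series[setdiff(names(series), drop_markers)]

  data <- purrr::map_dfr(names(series), function(key) {
    parts <- strsplit(key, ".", fixed = TRUE)[[1]]
    m <- series[[key]]
    tibble::tibble(frame = seq_len(n), time_s = t, marker = parts[1],
                   side = parts[2], x = m[, 1], y = m[, 2], z = m[, 3])
  })

  trial <- marker_trial(data, participant_id, group, paretic_side,
                        belt_speed = p$belt_speed, sampling_rate = p$sampling_rate)

  truth <- list(
    params = p,
    events = ground_truth_events(p, duration),
    metrics = ground_truth_metrics(p, paretic_side)
  )
  list(trial = trial, truth = truth)
}

# exact event times implied by the analytic trajectory: foot strike at the
# stance onset (most anterior point), toe off at stance end (most posterior)
ground_truth_events <- function(p, duration) {
  margin <- 2 / p$sampling_rate
  out <- list()
  for (side in c("left", "right")) {
    f <- p[[paste0("stance_fraction_", side)]]
    k <- 0:(p$n_strides + 1)
    fs <- (k + PHASE[[side]]) * p$stride_time
    to <- (k + PHASE[[side]] + f) * p$stride_time
    out[[side]] <- list(
      foot_strike = fs[fs >= margin & fs <= duration - margin],
      toe_off = to[to >= margin & to <= duration - margin]
    )
  }
  out
}

# the seven metric values implied by the parameters, for the reference limb
ground_truth_metrics <- function(p, paretic_side = "none") {
  ps <- if (paretic_side %in% c("left", "right")) paretic_side else "right"
  ns <- setdiff(c("left", "right"), ps)
  f_p <- p[[paste0("stance_fraction_", ps)]]
  f_n <- p[[paste0("stance_fraction_", ns)]]
  sl_p <- p[[paste0("step_length_", ps)]]
  sl_n <- p[[paste0("step_length_", ns)]]
  tibble::tibble(
    sla = abs(sl_p - sl_n) / (sl_p + sl_n),
    dlsta = abs(f_p - f_n) / (f_p + f_n - 1),
    slsta = abs(f_p - f_n) / (2 - f_p - f_n),
    knee_flex_deg = p[[paste0("knee_flexion_peak_", ps)]],
    tla_deg = p[[paste0("tla_peak_", ps)]],
    circumduction_m = p[[paste0("circumduction_amp_", ps)]],
    hip_hike_deg = p[[paste0("hip_hike_amp_", ps)]]
  )
}
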