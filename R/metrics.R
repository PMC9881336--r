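#' Normalized limb asymmetry index
#'
#' `|p - n| / (p + n)`: bounded in \[0, 1\], unitless, and invariant to
#' which limb is labelled paretic. For neurotypical participants the
#' "paretic" slot is filled by the right limb by convention.
#'
#' @param paretic_value,nonparetic_value Positive values (durations,
#'   lengths) for the paretic and non-paretic limb. Vectorized.
#' @return The asymmetry index.
#' @examples
#' asymmetry_index(0.6, 0.4)  # 0.2
#' @export
asymmetry_index <- function(paretic_value, nonparetic_value) {
  if (any(!is.finite(paretic_value) | paretic_value <= 0) ||
      any(!is.finite(nonparetic_value) | nonparetic_value <= 0)) {
    stop("asymmetry_index requires positive inputs")
  }
  abs(paretic_value - nonparetic_value) / (paretic_value + nonparetic_value)
}

#' Per-stride step lengths
#'
#' Step length of a limb at its foot strike is the fore-aft (X) distance
#' from its lateral malleolus to the contralateral malleolus at that frame.
#' Negative values (a "step-to" pattern, where the stepping foot does not
#' pass the stance foot) are flagged and kept with their magnitude.
#'
#' @param trial A [marker_trial()].
#' @param strides Stride table from [build_stride_table()].
#' @return Tibble with columns `side`, `stride`, `fs_frame`, `step_length`
#'   (m, magnitude), `step_to` (logical flag for negative raw values).
#' @export
step_lengths <- function(trial, strides) {
  out <- list()
  for (s in unique(strides$side)) {
    own <- marker_xyz(trial, "lateral_malleolus", s)
    con <- marker_xyz(trial, "lateral_malleolus", other_side(s))
    if (is.null(own) || is.null(con)) {
      stop("lateral malleoli of both limbs are required for step lengths")
    }
    st <- strides[strides$side == s & !strides$flagged, ]
    raw <- own[st$fs_frame, "x"] - con[st$fs_frame, "x"]
    out[[s]] <- tibble::tibble(
      side = s, stride = st$stride, fs_frame = st$fs_frame,
      step_length = abs(raw), step_to = !is.na(raw) & raw < 0
    )
  }
  dplyr::bind_rows(out)
}

#' Temporal asymmetry indices
#'
#' Single-limb-support and (leading) double-limb-support durations are
#' averaged across unflagged strides per limb, then contrasted with the
#' [asymmetry_index()] (paretic vs non-paretic).
#'
#' @param strides Stride table from [build_stride_table()].
#' @param paretic_side `"left"`, `"right"` or `"none"` (right limb used).
#' @return Named list with elements `slsta` and `dlsta`.
#' @export
temporal_asymmetries <- function(strides, paretic_side = "none") {
  ps <- if (paretic_side %in% c("left", "right")) paretic_side else "right"
  ns <- other_side(ps)
  mean_of <- function(side, col) {
    v <- strides[strides$side == side & !strides$flagged, ][[col]]
    v <- v[is.finite(v)]
    if (length(v) < 2) return(NA_real_)
    mean(v)
  }
  ss_p <- mean_of(ps, "single_support"); ss_n <- mean_of(ns, "single_support")
  ds_p <- mean_of(ps, "double_support"); ds_n <- mean_of(ns, "double_support")
  list(
    slsta = if (anyNA(c(ss_p, ss_n))) NA_real_ else asymmetry_index(ss_p, ss_n),
    dlsta = if (anyNA(c(ds_p, ds_n))) NA_real_ else asymmetry_index(ds_p, ds_n)
  )
}

#' Knee flexion angle from three lateral markers
#'
#' The planar-projection proxy used with a five-marker lateral set: the
#' angle is 180 degrees minus the interior angle at the lateral femoral
#' epicondyle between the vectors to the greater trochanter and to the
#' lateral malleolus, so a straight leg reads 0 and flexion is positive.
#'
#' @param gt,lfe,lm n x 3 matrices (or length-3 vectors) of marker
#'   positions: greater trochanter, lateral femoral epicondyle, lateral
#'   malleolus.
#' @return Knee flexion in degrees, one value per row.
#' @examples
#' knee_flexion_angle(c(0, 0, 1), c(0, 0, 0.5), c(0, 0, 0))      # 0
#' knee_flexion_angle(c(0, 0, 0.5), c(0, 0, 0), c(0.5, 0, 0))    # 90
#' @export
knee_flexion_angle <- function(gt, lfe, lm) {
  as_mat <- function(v) if (is.null(dim(v))) matrix(v, 1, 3) else v
  gt <- as_mat(gt); lfe <- as_mat(lfe); lm <- as_mat(lm)
  v1 <- gt - lfe
  v2 <- lm - lfe
  cosang <- rowSums(v1 * v2) /
    (sqrt(rowSums(v1^2)) * sqrt(rowSums(v2^2)))
  interior <- acos(pmin(pmax(cosang, -1), 1)) * 180 / pi
  180 - interior
}

#' Peak swing-phase knee flexion
#'
#' Mean across unflagged strides of the maximum [knee_flexion_angle()]
#' during swing (toe off to the next foot strike). Strides whose swing
#' window contains missing samples are excluded.
#'
#' @param trial A [marker_trial()].
#' @param strides Stride table from [build_stride_table()].
#' @param limb `"left"` or `"right"`.
#' @return Peak swing knee flexion in degrees (NA when not computable).
#' @export
peak_swing_knee_flexion <- function(trial, strides, limb) {
  gt <- marker_xyz(trial, "greater_trochanter", limb)
  lfe <- marker_xyz(trial, "lateral_femoral_epicondyle", limb)
  lm <- marker_xyz(trial, "lateral_malleolus", limb)
  if (is.null(gt) || is.null(lfe) || is.null(lm)) return(NA_real_)
  st <- strides[strides$side == limb & !strides$flagged, ]
  peaks <- purrr::map_dbl(seq_len(nrow(st)), function(i) {
    w <- st$to_frame[i]:st$next_fs_frame[i]
    ang <- knee_flexion_angle(gt[w, , drop = FALSE], lfe[w, , drop = FALSE],
                              lm[w, , drop = FALSE])
    if (anyNA(ang)) return(NA_real_)
    max(ang)
  })
  peaks <- peaks[is.finite(peaks)]
  if (length(peaks) < 2) return(NA_real_)
  mean(peaks)
}

#' Trailing limb angle at toe off
#'
#' Sagittal-plane angle between the lab vertical and the vector from the
#' greater trochanter to the fifth metatarsal at the limb's toe-off frame,
#' positive when the foot is posterior to the hip; averaged across
#' unflagged strides.
#'
#' @inheritParams peak_swing_knee_flexion
#' @return Trailing limb angle in degrees (NA when not computable).
#' @export
trailing_limb_angle <- function(trial, strides, limb) {
  gt <- marker_xyz(trial, "greater_trochanter", limb)
  mt5 <- marker_xyz(trial, "fifth_metatarsal", limb)
  if (is.null(gt) || is.null(mt5)) return(NA_real_)
  st <- strides[strides$side == limb & !strides$flagged, ]
  ang <- purrr::map_dbl(seq_len(nrow(st)), function(i) {
    f <- st$to_frame[i]
    dx <- gt[f, "x"] - mt5[f, "x"]
    dz <- gt[f, "z"] - mt5[f, "z"]
    if (anyNA(c(dx, dz))) return(NA_real_)
    atan2(dx, dz) * 180 / pi
  })
  ang <- ang[is.finite(ang)]
  if (length(ang) < 2) return(NA_real_)
  mean(ang)
}

#' Swing-phase circumduction
#'
#' Per stride: the peak lateral (away from the midline) displacement of the
#' lateral malleolus during swing relative to that stride's mean
#' stance-phase lateral position; displacement toward the midline is
#' floored at zero. The metric is the mean across unflagged strides, in
#' metres.
#'
#' @inheritParams peak_swing_knee_flexion
#' @return Circumduction in metres (NA when not computable).
#' @export
circumduction <- function(trial, strides, limb) {
  lm <- marker_xyz(trial, "lateral_malleolus", limb)
  if (is.null(lm)) return(NA_real_)
  lat_sign <- if (limb == "left") 1 else -1
  st <- strides[strides$side == limb & !strides$flagged, ]
  vals <- purrr::map_dbl(seq_len(nrow(st)), function(i) {
    stance <- st$fs_frame[i]:st$to_frame[i]
    swing <- st$to_frame[i]:st$next_fs_frame[i]
    y0 <- mean(lm[stance, "y"], na.rm = TRUE)
    disp <- lat_sign * (lm[swing, "y"] - y0)
    if (anyNA(disp) || !is.finite(y0)) return(NA_real_)
    max(pmax(disp, 0))
  })
  vals <- vals[is.finite(vals)]
  if (length(vals) < 2) return(NA_real_)
  mean(vals)
}

#' Swing-phase hip hiking
#'
#' Frontal-plane pelvic obliquity is the angle of the inter-crest line,
#' signed positive when the metric limb's crest is higher. Per stride the
#' metric is the peak obliquity during the limb's swing minus a reference
#' obliquity (at the stride's initiating foot strike, when both feet are on
#' the ground and the pelvis is level, or the stance-phase mean), floored
#' at zero; averaged across unflagged strides, in degrees.
#'
#' @inheritParams peak_swing_knee_flexion
#' @param reference `"foot_strike"` (default) or `"stance_mean"`.
#' @return Hip hiking in degrees; NA when either iliac crest is missing.
#' @export
hip_hiking <- function(trial, strides, limb,
                       reference = c("foot_strike", "stance_mean")) {
  reference <- match.arg(reference)
  own <- marker_xyz(trial, "iliac_crest", limb)
  con <- marker_xyz(trial, "iliac_crest", other_side(limb))
  if (is.null(own) || is.null(con)) return(NA_real_)
  obliq <- atan2(own[, "z"] - con[, "z"], abs(own[, "y"] - con[, "y"])) * 180 / pi
  st <- strides[strides$side == limb & !strides$flagged, ]
  vals <- purrr::map_dbl(seq_len(nrow(st)), function(i) {
    swing <- st$to_frame[i]:st$next_fs_frame[i]
    ref <- switch(reference,
      foot_strike = obliq[st$fs_frame[i]],
      stance_mean = mean(obliq[st$fs_frame[i]:st$to_frame[i]], na.rm = TRUE)
    )
    pk <- suppressWarnings(max(obliq[swing], na.rm = TRUE))
    if (!is.finite(pk) || !is.finite(ref)) return(NA_real_)
    max(pk - ref, 0)
  })
  vals <- vals[is.finite(vals)]
  if (length(vals) < 2) return(NA_real_)
  mean(vals)
}

#' Compute the seven gait metrics for one trial
#'
#' Runs the full single-trial pipeline: optional zero-phase low-pass
#' filtering, analysis-window selection, bilateral event detection, stride
#' segmentation, and the seven metrics averaged across all strides whose
#' initiating foot strike falls inside the window. Intralimb metrics (knee
#' flexion, trailing limb angle, circumduction, hip hiking) are computed on
#' the paretic limb for stroke participants and the right limb otherwise.
#' A metric whose markers are missing is reported as `NA`; the record is
#' retained.
#'
#' @param trial A [marker_trial()].
#' @param bin_mode,bin_seconds Analysis window (see [select_analysis_bin()]).
#' @param filter_cutoff Low-pass cutoff in Hz, or `NULL` to skip filtering
#'   (appropriate for noiseless synthetic data).
#' @param filter_order Butterworth order per pass.
#' @param prominence,min_interval Event-detection thresholds
#'   (see [detect_events()]).
#' @param hip_hike_reference Reference posture for [hip_hiking()].
#' @return A one-row tibble: `participant_id`, `group`, `paretic_side`,
#'   `speed`, the seven metrics, `n_strides`. Per-stride diagnostics are
#'   attached as the `"stride_detail"` attribute.
#' @export
compute_gait_metrics <- function(trial, bin_mode = "whole", bin_seconds = 30,
                                 filter_cutoff = 6, filter_order = 4,
                                 prominence = 0.02, min_interval = 0.2,
                                 hip_hike_reference = "foot_strike") {
  stopifnot(inherits(trial, "marker_trial"))
  if (!is.null(filter_cutoff)) {
    trial <- lowpass_filter(trial, cutoff = filter_cutoff, order = filter_order)
  }
  bin <- select_analysis_bin(trial, bin_mode, bin_seconds)
  sides <- reference_sides(trial)

  events <- tryCatch(
    dplyr::bind_rows(
      detect_events(trial, "left", prominence = prominence, min_interval = min_interval),
      detect_events(trial, "right", prominence = prominence, min_interval = min_interval)
    ),
    error = function(e) NULL
  )
  na_record <- function(n_str = NA_integer_, detail = NULL) {
    rec <- tibble::tibble(
      participant_id = trial$participant_id, group = trial$group,
      paretic_side = trial$paretic_side, speed = trial$belt_speed,
      sla = NA_real_, dlsta = NA_real_, slsta = NA_real_,
      knee_flex_deg = NA_real_, tla_deg = NA_real_,
      circumduction_m = NA_real_, hip_hike_deg = NA_real_,
      n_strides = n_str
    )
    attr(rec, "stride_detail") <- detail
    rec
  }
  if (is.null(events)) return(na_record())

  strides <- build_stride_table(events, trial$sampling_rate)
  # a stride belongs to the window iff its initiating foot strike does
  # (start-inclusive)
  strides <- strides[strides$fs_frame >= bin$start & strides$fs_frame <= bin$end, ]
  if (nrow(strides[strides$side == sides$paretic & !strides$flagged, ]) < 2) {
    return(na_record(detail = strides))
  }

  sl <- tryCatch(step_lengths(trial, strides), error = function(e) NULL)
  sla <- if (is.null(sl)) NA_real_ else {
    mp <- mean(sl$step_length[sl$side == sides$paretic], na.rm = TRUE)
    mn <- mean(sl$step_length[sl$side == sides$nonparetic], na.rm = TRUE)
    if (is.finite(mp) && is.finite(mn) && mp > 0 && mn > 0) {
      asymmetry_index(mp, mn)
    } else NA_real_
  }
  ta <- temporal_asymmetries(strides, trial$paretic_side)

  rec <- tibble::tibble(
    participant_id = trial$participant_id, group = trial$group,
    paretic_side = trial$paretic_side, speed = trial$belt_speed,
    sla = sla, dlsta = ta$dlsta, slsta = ta$slsta,
    knee_flex_deg = peak_swing_knee_flexion(trial, strides, sides$paretic),
    tla_deg = trailing_limb_angle(trial, strides, sides$paretic),
    circumduction_m = circumduction(trial, strides, sides$paretic),
    hip_hike_deg = hip_hiking(trial, strides, sides$paretic,
                              reference = hip_hike_reference),
    n_strides = sum(strides$side == sides$paretic & !strides$flagged)
  )
  attr(rec, "stride_detail") <- strides
  rec
}

#' Apply the cohort inclusion filter
#'
#' Participants are retained only when their slowest walking speed is
#' strictly greater than `min_speed` (default 0.20 m/s) and a standing
#' calibration is available. Exclusion reasons are recorded rather than
#' rows silently dropped.
#'
#' @param meta Participant metadata tibble with either a `speeds` list
#'   column or `speed_*` columns, and optionally a logical
#'   `standing_calibration` column (assumed `TRUE` when absent).
#' @param min_speed Strict lower bound on the slowest speed, m/s.
#' @return `meta` with logical `included` and character `exclusion_reason`
#'   columns appended.
#' @export
apply_inclusion_filter <- function(meta, min_speed = 0.20) {
  speeds <- metadata_speeds(meta)
  slowest <- purrr::map_dbl(speeds, function(v) {
    v <- v[is.finite(v)]
    if (length(v) == 0) NA_real_ else min(v)
  })
  calib <- if ("standing_calibration" %in% names(meta)) {
    meta$standing_calibration
  } else rep(TRUE, nrow(meta))
  included <- !is.na(slowest) & slowest > min_speed & calib
  reason <- rep(NA_character_, nrow(meta))
  reason[is.na(slowest)] <- "no speeds recorded"
  reason[!is.na(slowest) & slowest <= min_speed] <-
    sprintf("slowest speed <= %.2f m/s", min_speed)
  reason[!calib & is.na(reason)] <- "no standing calibration"
  meta$included <- included
  meta$exclusion_reason <- reason
  meta
}

# list of per-participant speed vectors from either representation
metadata_speeds <- function(meta) {
  if ("speeds" %in% names(meta)) return(meta$speeds)
  cols <- grep("^speed_", names(meta), value = TRUE)
  if (length(cols) == 0) stop("metadata must contain a 'speeds' list column or speed_* columns")
  purrr::map(seq_len(nrow(meta)), function(i) {
    v <- as.numeric(unlist(meta[i, cols]))
    v[is.finite(v)]
  })
}
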