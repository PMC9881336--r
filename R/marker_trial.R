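#' Marker names used throughout the package
#'
#' The five-marker lower-limb set the pipeline operates on, tracked
#' bilaterally: iliac crest, greater trochanter, lateral femoral epicondyle,
#' lateral malleolus and fifth metatarsal head.
#'
#' @format Character vector of length 5.
#' @export
GAIT_MARKERS <- c(
  "iliac_crest", "greater_trochanter", "lateral_femoral_epicondyle",
  "lateral_malleolus", "fifth_metatarsal"
)

#' Construct a marker trial
#'
#' A `marker_trial` bundles the long-format marker trajectories of one
#' participant walking at one belt speed with the metadata the downstream
#' modules need. Positions are in metres in a lab frame with +X anterior
#' (direction of progression), +Y left and +Z up. Missing samples are `NA`,
#' never silently zero.
#'
#' @param data Tibble with columns `frame` (1-based sample index), `time_s`,
#'   `marker` (one of [GAIT_MARKERS]), `side` (`"left"`/`"right"`), `x`, `y`,
#'   `z` (metres).
#' @param participant_id Character scalar.
#' @param group `"stroke"` or `"neurotypical"`.
#' @param paretic_side `"left"`, `"right"` or `"none"`.
#' @param belt_speed Belt speed in m/s.
#' @param sampling_rate Sampling rate in Hz (>= 50).
#' @return An object of class `marker_trial`.
#' @export
marker_trial <- function(data, participant_id, group = c("neurotypical", "stroke"),
                         paretic_side = c("none", "left", "right"),
                         belt_speed, sampling_rate) {
  group <- match.arg(group)
  paretic_side <- match.arg(paretic_side)
  stopifnot(is.numeric(belt_speed), belt_speed > 0,
            is.numeric(sampling_rate), sampling_rate > 0)
  needed <- c("frame", "time_s", "marker", "side", "x", "y", "z")
  if (!all(needed %in% names(data))) {
    stop("trial data must have columns: ", paste(needed, collapse = ", "))
  }
  data <- tibble::as_tibble(data)
  counts <- dplyr::count(data, .data$marker, .data$side)
  if (nrow(counts) > 0 && length(unique(counts$n)) != 1) {
    stop("all marker series must share the same frame count")
  }
  structure(
    list(
      participant_id = as.character(participant_id),
      group = group,
      paretic_side = paretic_side,
      belt_speed = belt_speed,
      sampling_rate = sampling_rate,
      frame_count = if (nrow(counts) > 0) counts$n[1] else 0L,
      data = data
    ),
    class = "marker_trial"
  )
}

#' @export
print.marker_trial <- function(x, ...) {
  cat("<marker_trial> participant", x$participant_id,
      sprintf("(%s, paretic side %s)\n", x$group, x$paretic_side))
  cat(sprintf("  belt speed %.2f m/s, %d frames @ %g Hz (%.1f s)\n",
              x$belt_speed, x$frame_count, x$sampling_rate,
              x$frame_count / x$sampling_rate))
  pres <- unique(paste(x$data$marker, x$data$side, sep = "/"))
  cat("  markers:", length(pres), "series\n")
  invisible(x)
}

#' Extract one marker series as an n x 3 matrix
#'
#' @param trial A [marker_trial()].
#' @param marker Marker name (see [GAIT_MARKERS]).
#' @param side `"left"` or `"right"`.
#' @return Numeric matrix with columns `x`, `y`, `z` and one row per frame,
#'   or `NULL` when the series is absent from the trial.
#' @export
marker_xyz <- function(trial, marker, side) {
  d <- trial$data[trial$data$marker == marker & trial$data$side == side, ]
  if (nrow(d) == 0) return(NULL)
  d <- d[order(d$frame), ]
  m <- cbind(x = d$x, y = d$y, z = d$z)
  rownames(m) <- NULL
  m
}

#' List marker series present in a trial
#' @param trial A [marker_trial()].
#' @return Tibble with columns `marker`, `side`.
#' @export
trial_markers <- function(trial) {
  dplyr::distinct(trial$data, .data$marker, .data$side)
}

has_marker <- function(trial, marker, side) {
  any(trial$data$marker == marker & trial$data$side == side)
}

#' Paretic and non-paretic reference sides for a trial
#'
#' Intralimb metrics are computed on the paretic limb for participants
#' post-stroke and on the right limb for neurotypical participants; the
#' contralateral limb is the non-paretic reference.
#'
#' @param trial A [marker_trial()].
#' @return Named list with `paretic` and `nonparetic` side labels.
#' @export
reference_sides <- function(trial) {
  p <- if (trial$paretic_side %in% c("left", "right")) trial$paretic_side else "right"
  list(paretic = p, nonparetic = setdiff(c("left", "right"), p))
}

other_side <- function(side) setdiff(c("left", "right"), side)
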