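#' Detect foot-strike and toe-off events from malleolus kinematics
#'
#' On a treadmill the body stays roughly stationary while the belt carries
#' the stance foot rearward, so foot strike and toe off are the most
#' anterior and most posterior positions of the lateral malleolus. Events
#' are located at sign changes of the discrete fore-aft derivative, refined
#' to the extreme sample, and cleaned with a minimum-prominence threshold
#' and a minimum inter-event interval; alternation (strike, toe off,
#' strike, ...) is enforced by keeping the more extreme of two same-type
#' neighbours.
#'
#' @param trial A [marker_trial()] (low-pass filtered for noisy data).
#' @param side `"left"` or `"right"`.
#' @param bin Optional analysis window from [select_analysis_bin()]; events
#'   are detected within it. Default: the whole trial.
#' @param prominence Minimum fore-aft amplitude (m) between neighbouring
#'   opposite-type events; smaller wiggles are discarded.
#' @param min_interval Minimum time (s) between neighbouring events.
#' @return Tibble with columns `side`, `event` (`"foot_strike"` /
#'   `"toe_off"`), `frame` (1-based sample index) and `time_s`.
#' @export
detect_events <- function(trial, side = c("left", "right"), bin = NULL,
                          prominence = 0.02, min_interval = 0.2) {
  side <- match.arg(side)
  m <- marker_xyz(trial, "lateral_malleolus", side)
  if (is.null(m)) stop("lateral_malleolus missing on side ", side)
  frames <- seq_len(nrow(m))
  if (!is.null(bin)) frames <- frames[frames >= bin$start & frames <= bin$end]
  x <- m[frames, "x"]

  ev <- NULL
  for (run in finite_runs(x)) {
    if (length(run) < 3) next
    cand <- local_extrema(x[run])
    if (nrow(cand) == 0) next
    cand$frame <- frames[run][cand$idx]
    ev <- rbind(ev, cand[c("frame", "type", "value")])
  }
  if (is.null(ev) || nrow(ev) == 0) stop("insufficient strides: no fore-aft extrema found")
  ev <- ev[order(ev$frame), ]
  ev <- enforce_alternation(ev)
  ev <- prune_events(ev, prominence, min_interval * trial$sampling_rate)

  n_fs <- sum(ev$type == "max")
  if (n_fs < 3) stop("insufficient strides: fewer than 2 complete strides in bin")

  # sub-sample refinement: intersect one-sided secants around the extreme
  # sample. Fore-aft extrema of treadmill gait are corners (constant belt
  # retreat meeting a flat swing reversal), where the plain argmax is biased
  # half a frame toward the flat side; the secant intersection recovers the
  # corner, and reduces to the vertex for smooth extrema.
  pos <- match(ev$frame, frames)
  t_ref <- vapply(pos, function(m) refine_extremum(x, m), numeric(1))
  frame_ref <- frames[1] - 1 + t_ref
  tibble::tibble(
    side = side,
    event = ifelse(ev$type == "max", "foot_strike", "toe_off"),
    frame = as.integer(round(frame_ref)),
    time_s = (frame_ref - 1) / trial$sampling_rate
  )
}

# Sub-sample extremum location around the extreme sample m. Treadmill
# fore-aft extrema are one-sided corners: a linear belt retreat meeting a
# locally quadratic swing reversal. The vertex of a parabola fitted to the
# three samples on the flatter (quadratic) side locates the corner; for a
# near-symmetric smooth extremum the centred three-point parabola is used
# instead. Falls back to m when undecidable.
refine_extremum <- function(x, m) {
  n <- length(x)
  if (m - 3 < 1 || m + 3 > n) return(m)
  w <- x[(m - 3):(m + 3)]
  if (anyNA(w)) return(m)
  sl <- x[m - 1] - x[m - 2]
  sr <- x[m + 2] - x[m + 1]
  amax <- max(abs(sl), abs(sr)); amin <- min(abs(sl), abs(sr))
  if (amax < 1e-12) return(m)
  vertex3 <- function(p1, p2, p3) {
    den <- p1 - 2 * p2 + p3
    if (abs(den) < 1e-15) return(NA_real_)
    (p1 - p3) / (2 * den)
  }
  t_star <- if (amin / amax >= 0.9) {
    m + vertex3(x[m - 1], x[m], x[m + 1])
  } else if (abs(sr) < abs(sl)) {
    (m + 2) + vertex3(x[m + 1], x[m + 2], x[m + 3])
  } else {
    (m - 2) + vertex3(x[m - 3], x[m - 2], x[m - 1])
  }
  if (!is.finite(t_star) || abs(t_star - m) > 1.2) return(m)
  t_star
}

# candidate extrema of a finite series by derivative sign change,
# plateau-aware, refined to the extreme sample in a +/-2 neighbourhood
local_extrema <- function(x) {
  n <- length(x)
  s <- sign(diff(x))
  nz <- which(s != 0)
  if (length(nz) < 2) return(data.frame(idx = integer(), type = character(), value = numeric()))
  # carry the previous non-zero sign across plateaus
  s_f <- s
  last <- s[nz[1]]
  for (i in seq_along(s_f)) {
    if (s_f[i] == 0) s_f[i] <- last else last <- s_f[i]
  }
  idx <- integer(); type <- character()
  for (i in seq_len(n - 2)) {
    if (s_f[i] > 0 && s_f[i + 1] < 0) { idx <- c(idx, i + 1); type <- c(type, "max") }
    if (s_f[i] < 0 && s_f[i + 1] > 0) { idx <- c(idx, i + 1); type <- c(type, "min") }
  }
  if (length(idx) == 0) return(data.frame(idx = integer(), type = character(), value = numeric()))
  refined <- vapply(seq_along(idx), function(k) {
    lo <- max(1, idx[k] - 2); hi <- min(n, idx[k] + 2)
    w <- lo:hi
    if (type[k] == "max") w[which.max(x[w])] else w[which.min(x[w])]
  }, integer(1))
  data.frame(idx = refined, type = type, value = x[refined])
}

# keep the more extreme of adjacent same-type events
enforce_alternation <- function(ev) {
  repeat {
    if (nrow(ev) < 2) return(ev)
    dup <- which(ev$type[-1] == ev$type[-nrow(ev)])
    if (length(dup) == 0) return(ev)
    i <- dup[1]
    a <- ev[i, ]; b <- ev[i + 1, ]
    drop <- if (a$type == "max") {
      if (a$value >= b$value) i + 1 else i
    } else {
      if (a$value <= b$value) i + 1 else i
    }
    ev <- ev[-drop, ]
  }
}

# iteratively remove low-prominence / too-close adjacent event pairs
prune_events <- function(ev, prominence, min_frames) {
  repeat {
    if (nrow(ev) < 2) return(ev)
    amp <- abs(diff(ev$value))
    gap <- diff(ev$frame)
    bad <- which(amp < prominence | gap < min_frames)
    if (length(bad) == 0) return(ev)
    i <- bad[which.min(amp[bad])]
    ev <- ev[-c(i, i + 1), ]
    ev <- enforce_alternation(ev)
  }
}

#' Build a per-stride table from bilateral gait events
#'
#' Segments each limb's events into strides (foot strike to next foot
#' strike) and derives the temporal structure of each stride: stance time
#' (strike to toe off), swing time (toe off to next strike), single-limb
#' support (the contralateral swing that falls inside this limb's stance)
#' and leading double-limb support (this limb's strike to the contralateral
#' toe off). Strides violating the physiological event ordering (e.g. the
#' contralateral strike falling outside stance) are flagged, not dropped.
#'
#' @param events Tibble of events for both limbs, as returned by binding
#'   two [detect_events()] results.
#' @param sampling_rate Sampling rate in Hz.
#' @return Tibble with one row per stride and columns `side`, `stride`,
#'   `fs_frame`, `to_frame`, `next_fs_frame`, `contra_fs_frame`,
#'   `contra_to_frame`, `stride_time`, `stance_time`, `swing_time`,
#'   `double_support`, `single_support`, `flagged`, `flag_reason`
#'   (durations in seconds).
#' @export
build_stride_table <- function(events, sampling_rate) {
  stopifnot(all(c("side", "event", "frame") %in% names(events)))
  events <- events[order(events$frame), ]
  if (!"time_s" %in% names(events)) {
    events$time_s <- (events$frame - 1) / sampling_rate
  }
  rows <- list()
  for (s in unique(events$side)) {
    own <- events[events$side == s, ]
    con <- events[events$side == other_side(s), ]
    fs <- own[own$event == "foot_strike", ]
    to <- own[own$event == "toe_off", ]
    if (nrow(fs) < 2) stop("need at least 2 foot strikes per limb (side ", s, ")")
    cfs <- con[con$event == "foot_strike", ]
    cto <- con[con$event == "toe_off", ]
    for (i in seq_len(nrow(fs) - 1)) {
      f1 <- fs$frame[i]; f2 <- fs$frame[i + 1]
      t1 <- fs$time_s[i]; t2 <- fs$time_s[i + 1]
      oto <- to[to$frame > f1 & to$frame < f2, ]
      flagged <- FALSE; reason <- NA_character_
      if (nrow(oto) != 1) {
        flagged <- TRUE; reason <- "missing or duplicated toe-off within stride"
        oto <- oto[0, ]
      }
      kfs <- cfs[cfs$frame > f1 & cfs$frame < f2, ]
      kfs <- if (nrow(kfs) >= 1) kfs[1, ] else kfs
      kto <- if (nrow(kfs) == 1) {
        v <- cto[cto$frame > f1 & cto$frame < kfs$frame, ]
        if (nrow(v) >= 1) v[nrow(v), ] else v
      } else cto[0, ]
      if (!flagged && (nrow(kfs) == 0 || nrow(oto) == 0 || kfs$frame >= oto$frame)) {
        flagged <- TRUE
        reason <- "contralateral foot strike outside ipsilateral stance"
      }
      if (!flagged && nrow(kto) == 0) {
        flagged <- TRUE
        reason <- "contralateral toe-off missing before contralateral strike"
      }
      has <- function(d) nrow(d) == 1
      rows[[length(rows) + 1]] <- tibble::tibble(
        side = s, stride = i,
        fs_frame = as.integer(f1),
        to_frame = if (has(oto)) as.integer(oto$frame) else NA_integer_,
        next_fs_frame = as.integer(f2),
        contra_fs_frame = if (has(kfs)) as.integer(kfs$frame) else NA_integer_,
        contra_to_frame = if (has(kto)) as.integer(kto$frame) else NA_integer_,
        stride_time = t2 - t1,
        stance_time = if (has(oto)) oto$time_s - t1 else NA_real_,
        swing_time = if (has(oto)) t2 - oto$time_s else NA_real_,
        double_support = if (has(kto)) kto$time_s - t1 else NA_real_,
        single_support = if (has(kfs) && has(kto)) kfs$time_s - kto$time_s else NA_real_,
        flagged = flagged, flag_reason = reason
      )
    }
  }
  dplyr::bind_rows(rows)
}

#' Export events as an audit table
#'
#' @param events Tibble from [detect_events()].
#' @param path CSV destination.
#' @return `path`, invisibly.
#' @export
write_events_csv <- function(events, path) {
  utils::write.csv(events[, c("side", "event", "frame", "time_s")], path,
                   row.names = FALSE)
  invisible(path)
}
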