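#' Zero-phase Butterworth low-pass filter for marker trajectories
#'
#' Filters every coordinate series of a trial with a forward-backward
#' (zero-phase) Butterworth low-pass. The dual pass squares the magnitude
#' response and cancels phase distortion, so event timing is preserved.
#' Endpoints are handled with odd-reflective padding. Flagged-missing (`NA`)
#' spans are excluded from filtering and remain flagged; each contiguous
#' finite run is filtered independently.
#'
#' @param trial A [marker_trial()].
#' @param cutoff Low-pass cutoff in Hz (default 6, the standard choice for
#'   gait kinematics). Must be below the Nyquist frequency.
#' @param order Butterworth order of each pass (default 4).
#' @return A new, filtered [marker_trial()].
#' @export
lowpass_filter <- function(trial, cutoff = 6, order = 4) {
  stopifnot(inherits(trial, "marker_trial"))
  nyquist <- trial$sampling_rate / 2
  if (cutoff >= nyquist) {
    stop(sprintf("cutoff (%g Hz) must be below the Nyquist frequency (%g Hz)",
                 cutoff, nyquist))
  }
  bf <- signal::butter(order, cutoff / nyquist, type = "low")
  data <- trial$data
  data <- dplyr::group_by(data, .data$marker, .data$side)
  data <- dplyr::mutate(data,
    x = filtfilt_series(.data$x, bf, order),
    y = filtfilt_series(.data$y, bf, order),
    z = filtfilt_series(.data$z, bf, order)
  )
  data <- dplyr::ungroup(data)
  out <- trial
  out$data <- data
  out
}

# forward-backward filtering of one series with odd-reflective padding,
# applied independently to each contiguous finite run
filtfilt_series <- function(x, bf, order) {
  out <- x
  runs <- finite_runs(x)
  for (r in runs) {
    seg <- x[r]
    n <- length(seg)
    if (n < 2) next
    pad <- min(n - 1, max(3 * (order + 1), 50))
    left <- 2 * seg[1] - seg[seq(pad + 1, 2)]
    right <- 2 * seg[n] - seg[seq(n - 1, n - pad)]
    # remove the segment mean so the zero-state filter start-up transient
    # acts on a zero-mean signal (exact unit DC gain for constants)
    m <- mean(seg)
    ext <- c(left, seg, right) - m
    fwd <- signal::filter(bf, ext)
    rev_ <- rev(signal::filter(bf, rev(fwd)))
    out[r] <- rev_[(pad + 1):(pad + n)] + m
  }
  out
}

# list of index vectors for maximal runs of finite values
finite_runs <- function(x) {
  ok <- is.finite(x)
  if (!any(ok)) return(list())
  r <- rle(ok)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  purrr::map2(starts[r$values], ends[r$values], seq)
}

#' Select the analysis window of a trial
#'
#' Returns the frame interval over which strides are analyzed. Typical
#' protocols record long treadmill trials but analyze the middle or final
#' thirty seconds; metrics are then averaged across all strides initiated
#' inside the window.
#'
#' @param trial A [marker_trial()].
#' @param mode `"whole"`, `"middle"` or `"final"`.
#' @param seconds Window length in seconds for `"middle"`/`"final"`.
#' @return A list with 1-based inclusive `start` and `end` frame indices and
#'   the window length `n` in frames. In 0-based half-open convention the
#'   window is `[start - 1, end)`.
#' @examples
#' # a 300 s trial at 100 Hz: the middle 30 s spans frames 13501..16500
#' @export
select_analysis_bin <- function(trial, mode = c("whole", "middle", "final"),
                                seconds = 30) {
  mode <- match.arg(mode)
  n_frames <- trial$frame_count
  if (mode == "whole") {
    return(list(start = 1L, end = n_frames, n = n_frames))
  }
  span <- round(seconds * trial$sampling_rate)
  if (span > n_frames) {
    stop(sprintf("requested %g s window exceeds the trial duration (%.1f s)",
                 seconds, n_frames / trial$sampling_rate))
  }
  start0 <- switch(mode,
    middle = floor((n_frames - span) / 2),
    final = n_frames - span
  )
  list(start = as.integer(start0 + 1), end = as.integer(start0 + span),
       n = as.integer(span))
}
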