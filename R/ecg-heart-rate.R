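#' Detect QRS complexes in a raw ECG trace
#'
#' Pan-Tompkins-style detector: zero-phase band-pass (default 5-40 Hz,
#' 2nd-order Butterworth applied forwards and backwards), squared
#' derivative, moving-window integration, then an adaptive threshold with
#' a refractory period of `60 / hr_max` seconds.  When a synchronized
#' dynamic-heave series is supplied, the threshold is raised in windows of
#' high flight activity, because flapping injects motion artifacts into
#' the electrode signal.  Detected peaks are refined to the local maximum
#' of the band-passed signal.
#'
#' A flat-line or structureless (all-noise) trace yields an empty beat
#' series with a `diagnostic` attribute rather than an error.
#'
#' @param ecg an `ecg_trace` (see [generate_ecg()] and [read_ecg_csv()]).
#' @param heave_dynamic optional numeric vector, dynamic heave in g at the
#'   ECG sampling rate, used to adapt the detection threshold to activity.
#' @param hr_max maximum physiological rate in bpm; sets the refractory
#'   period (default 800 bpm, i.e. 75 ms).
#' @param band band-pass corner frequencies in Hz.
#' @param integration_window moving-window integration length, seconds.
#' @param threshold_frac detection threshold as a fraction of the 99th
#'   percentile of the integrated signal.
#' @param activity_gain threshold inflation per g of local mean dynamic
#'   heave magnitude.
#' @param snr_min minimum ratio of the integrated signal's 99th percentile
#'   to its median for the trace to count as containing beats at all.
#' @return A `beat_series`: data frame with `time_s` (time of each beat
#'   closing an inter-beat interval) and `hr_bpm` (60 / interval).  The
#'   full R-time vector is kept in attribute `r_times`.
#' @export
detect_qrs <- function(ecg, heave_dynamic = NULL, hr_max = 800,
                       band = c(5, 40), integration_window = 0.02,
                       threshold_frac = 0.3, activity_gain = 2,
                       snr_min = 8) {
  stopifnot(inherits(ecg, "ecg_trace"))
  x <- ecg$ecg_mV
  fs <- ecg$sampling_rate
  if (fs < 200) stop("sampling rate must be at least 200 Hz")
  if (length(x) < 2 * fs) stop("trace must be at least 2 s long")
  if (!is.null(heave_dynamic) && length(heave_dynamic) != length(x)) {
    stop("heave_dynamic must match the ECG sample count")
  }

  bf <- signal::butter(2, band / (fs / 2), type = "pass")
  xf <- signal::filtfilt(bf, x)
  sq <- (c(0, diff(xf)) * fs)^2
  w <- max(1L, round(integration_window * fs))
  f <- runmean_centered(sq, halfwidth = w %/% 2L)

  q99 <- stats::quantile(f, 0.99, names = FALSE)
  if (q99 <= snr_min * stats::median(f) + 1e-12) {
    return(empty_beat_series("no QRS-like structure found (flat or all-noise trace)"))
  }
  thr <- rep(threshold_frac * q99, length(f))
  if (!is.null(heave_dynamic)) {
    act <- runmean_centered(abs(heave_dynamic), halfwidth = as.integer(fs) %/% 2L)
    thr <- thr * (1 + activity_gain * act)
  }

  is_peak <- f > thr &
    f >= c(-Inf, f[-length(f)]) &
    f >= c(f[-1], -Inf)
  cand <- which(is_peak)
  if (!length(cand)) {
    return(empty_beat_series("no peaks above the adaptive threshold"))
  }
  # refractory pruning: within 60/hr_max s keep the stronger peak
  refr <- round(60 / hr_max * fs)
  keep <- integer(0)
  last <- -Inf
  for (i in cand) {
    if (i - last >= refr) {
      keep <- c(keep, i)
      last <- i
    } else if (f[i] > f[keep[length(keep)]]) {
      keep[length(keep)] <- i
      last <- i
    }
  }
  # refine each peak to the local band-passed extremum
  half <- round(0.03 * fs)
  n <- length(xf)
  ref_idx <- vapply(keep, function(i) {
    idx <- max(1, i - half):min(n, i + half)
    idx[which.max(abs(xf[idx]))]
  }, integer(1))
  r_times <- ecg$time_s[sort(unique(ref_idx))]
  beat_series(r_times)
}

beat_series <- function(r_times, diagnostic = NULL) {
  hr <- if (length(r_times) >= 2) 60 / diff(r_times) else numeric(0)
  out <- data.frame(
    time_s = if (length(r_times) >= 2) r_times[-1] else numeric(0),
    hr_bpm = hr
  )
  attr(out, "r_times") <- r_times
  if (!is.null(diagnostic)) attr(out, "diagnostic") <- diagnostic
  class(out) <- c("beat_series", "data.frame")
  out
}

empty_beat_series <- function(diagnostic) beat_series(numeric(0), diagnostic)

#' Keep only beats inside dense (time, heart-rate) neighborhoods
#'
#' Each beat is ranked by its neighbor count: the number of other beats
#' within `+/- time_window` seconds and `+/- hr_window` bpm.  The top
#' `keep_fraction` of beats by count is retained (ties at the cutoff count
#' are all kept, so at least `ceiling(keep_fraction * n)` beats survive),
#' preserving temporal order.  Isolated spurious detections fall in sparse
#' regions of the (time, rate) plane and are removed.
#'
#' @param beats a `beat_series`.
#' @param time_window,hr_window neighborhood half-widths (s, bpm).
#' @param keep_fraction fraction of beats to retain, in (0, 1].
#' @return The filtered `beat_series`; the number of removed beats is in
#'   attribute `n_removed`.
#' @export
density_filter <- function(beats, time_window = 2, hr_window = 20,
                           keep_fraction = 0.95) {
  stopifnot(inherits(beats, "beat_series"))
  stop_if_not_scalar_pos(time_window, "time_window")
  stop_if_not_scalar_pos(hr_window, "hr_window")
  if (keep_fraction <= 0 || keep_fraction > 1) {
    stop("`keep_fraction` must be in (0, 1]")
  }
  n <- nrow(beats)
  if (n == 0L) stop("`beats` is empty")
  counts <- neighbor_counts(beats$time_s, beats$hr_bpm, time_window, hr_window)
  m <- ceiling(keep_fraction * n)
  cutoff <- sort(counts, decreasing = TRUE)[m]
  keep <- counts >= cutoff
  out <- beats[keep, , drop = FALSE]
  attr(out, "n_removed") <- n - sum(keep)
  class(out) <- c("beat_series", "data.frame")
  out
}

# Neighbor counts via a sorted two-pointer sweep over time, O(n * window).
neighbor_counts <- function(time_s, hr_bpm, time_window, hr_window) {
  n <- length(time_s)
  ord <- order(time_s)
  ts <- time_s[ord]
  hs <- hr_bpm[ord]
  counts <- integer(n)
  lo <- findInterval(ts - time_window, ts, left.open = TRUE) + 1L
  hi <- findInterval(ts + time_window, ts)
  for (i in seq_len(n)) {
    j <- lo[i]:hi[i]
    counts[ord[i]] <- sum(abs(hs[j] - hs[i]) <= hr_window) - 1L
  }
  counts
}

#' Drop beats outside a physiological heart-rate window
#'
#' Deterministic replacement for manual visual outlier deletion: beats
#' whose instantaneous rate falls outside `[hr_min, hr_max]` are removed
#' and counted.
#'
#' @param beats a `beat_series`.
#' @param hr_min,hr_max physiological window in bpm (default 60-800).
#' @return The filtered `beat_series` with attribute `n_removed`.
#' @export
remove_outliers <- function(beats, hr_min = 60, hr_max = 800) {
  stopifnot(inherits(beats, "beat_series"))
  stop_if_not_scalar_pos(hr_min, "hr_min")
  if (hr_min >= hr_max) stop("`hr_min` must be below `hr_max`")
  keep <- beats$hr_bpm >= hr_min & beats$hr_bpm <= hr_max
  out <- beats[keep, , drop = FALSE]
  attr(out, "n_removed") <- sum(!keep)
  class(out) <- c("beat_series", "data.frame")
  out
}

#' Resample beat-wise heart rate onto a uniform 5 Hz grid
#'
#' Zero-order hold: each grid point takes the rate of the most recent
#' completed inter-beat interval.  Grid points farther than `max_gap`
#' seconds from the previous beat (for example inside a detection dropout)
#' are emitted as missing rather than interpolated.
#'
#' @param beats a `beat_series` with at least 2 beats.
#' @param rate output rate in Hz (default 5).
#' @param max_gap longest beat-free interval bridged by the hold, seconds.
#' @param t_start,t_end grid limits in seconds; default session start (0)
#'   to the last beat.
#' @return An `hr_series`: data frame with `time_s` (uniform grid),
#'   `hr_bpm` (NA where missing) and `quality` (`"ok"` or `"gap"`).
#' @export
resample_hr <- function(beats, rate = 5, max_gap = 2, t_start = 0,
                        t_end = NULL) {
  stopifnot(inherits(beats, "beat_series"))
  if (nrow(beats) < 1L) {
    stop("at least 2 beats (one inter-beat interval) are required")
  }
  stop_if_not_scalar_pos(rate, "rate")
  step <- 1 / rate
  t_end <- t_end %||% max(beats$time_s)
  grid <- seq(ceiling(t_start / step) * step, floor(t_end / step) * step,
              by = step)
  idx <- findInterval(grid + 1e-9, beats$time_s)
  hr <- ifelse(idx >= 1L, beats$hr_bpm[pmax(idx, 1L)], NA_real_)
  gap <- idx < 1L | (grid - beats$time_s[pmax(idx, 1L)]) > max_gap
  hr[gap] <- NA_real_
  structure(
    data.frame(time_s = grid, hr_bpm = hr,
               quality = ifelse(gap, "gap", "ok")),
    class = c("hr_series", "data.frame")
  )
}

#' Full ECG-to-heart-rate extraction pipeline
#'
#' Chains [detect_qrs()], [density_filter()], [remove_outliers()] and
#' [resample_hr()] with their defaults: raw ECG in, cleaned 5 Hz heart
#' rate out.
#'
#' @inheritParams detect_qrs
#' @inheritParams density_filter
#' @inheritParams remove_outliers
#' @inheritParams resample_hr
#' @return An `hr_series` (empty, with a `diagnostic` attribute, when no
#'   usable beats were found).
#' @export
extract_heart_rate <- function(ecg, heave_dynamic = NULL, time_window = 2,
                               hr_window = 20, keep_fraction = 0.95,
                               hr_min = 60, hr_max = 800, rate = 5,
                               max_gap = 2, t_start = 0, t_end = NULL) {
  beats <- detect_qrs(ecg, heave_dynamic = heave_dynamic, hr_max = hr_max)
  if (nrow(beats) < 2L) {
    out <- structure(
      data.frame(time_s = numeric(0), hr_bpm = numeric(0),
                 quality = character(0)),
      class = c("hr_series", "data.frame")
    )
    attr(out, "diagnostic") <- attr(beats, "diagnostic") %||% "fewer than 2 beats"
    return(out)
  }
  beats <- density_filter(beats, time_window, hr_window, keep_fraction)
  beats <- remove_outliers(beats, hr_min, hr_max)
  resample_hr(beats, rate = rate, max_gap = max_gap, t_start = t_start,
              t_end = t_end)
}
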