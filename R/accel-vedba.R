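#' Static (gravity) component of a tri-axial acceleration trace
#'
#' Smooths each axis with a centered running mean over `window` seconds
#' (default 1 s).  At the edges the window shrinks symmetrically rather
#' than padding with invented values, so the output has the input's
#' length.
#'
#' @param trace an `accel_trace`.
#' @param window smoothing window in seconds.
#' @return List with numeric vectors `surge_g`, `sway_g`, `heave_g`.
#' @export
static_acceleration <- function(trace, window = 1) {
  stopifnot(inherits(trace, "accel_trace"))
  stop_if_not_scalar_pos(window, "window")
  n <- length(trace$heave_g)
  w <- round(window * trace$sampling_rate)
  if (w > n) stop("window longer than the trace")
  h <- w %/% 2L
  list(
    surge_g = runmean_centered(trace$surge_g, h),
    sway_g = runmean_centered(trace$sway_g, h),
    heave_g = runmean_centered(trace$heave_g, h)
  )
}

#' Dynamic (movement) component: raw minus static acceleration
#'
#' @param trace an `accel_trace`.
#' @param static output of [static_acceleration()] on the same trace.
#' @return List with `surge_g`, `sway_g`, `heave_g` dynamic components.
#' @export
dynamic_acceleration <- function(trace, static) {
  stopifnot(inherits(trace, "accel_trace"))
  if (length(static$heave_g) != length(trace$heave_g)) {
    stop("static and raw series have different lengths")
  }
  list(
    surge_g = trace$surge_g - static$surge_g,
    sway_g = trace$sway_g - static$sway_g,
    heave_g = trace$heave_g - static$heave_g
  )
}

#' Vectorial dynamic body acceleration (VeDBA)
#'
#' Per-sample Euclidean norm of the three dynamic axes,
#' `sqrt(dx^2 + dy^2 + dz^2)`, reported in milli-g.
#'
#' @param dynamic list with `surge_g`, `sway_g`, `heave_g` (in g).
#' @return Numeric vector of VeDBA in mg.
#' @export
vedba <- function(dynamic) {
  if (length(unique(lengths(dynamic[c("surge_g", "sway_g", "heave_g")]))) != 1L) {
    stop("dynamic axes have different lengths")
  }
  1000 * sqrt(dynamic$surge_g^2 + dynamic$sway_g^2 + dynamic$heave_g^2)
}

#' Sub-sample a high-rate series to 1 Hz by decimation
#'
#' Retains the sample nearest each integer second (point sub-sampling,
#' not block averaging), matching the time step of the processed heart
#' rate.  Output timestamps are exact integer seconds.
#'
#' @param x numeric series (e.g. VeDBA in mg).
#' @param time_s sample times in seconds (uniform grid).
#' @param sampling_rate input rate in Hz (>= 1).
#' @return A `vedba_series`: data frame with integer-second `time_s` and
#'   `vedba_mg`.
#' @export
subsample_to_1hz <- function(x, time_s, sampling_rate) {
  if (!length(x)) stop("empty input")
  stopifnot(length(x) == length(time_s))
  if (sampling_rate < 1) stop("input rate must be at least 1 Hz")
  secs <- seq(ceiling(min(time_s) - 1e-9), floor(max(time_s) + 1e-9))
  idx <- round((secs - time_s[1]) * sampling_rate) + 1L
  idx <- pmin(pmax(idx, 1L), length(x))
  structure(
    data.frame(time_s = secs, vedba_mg = x[idx]),
    class = c("vedba_series", "data.frame")
  )
}

#' Raw acceleration to 1 Hz VeDBA in one call
#'
#' Chains [static_acceleration()], [dynamic_acceleration()], [vedba()]
#' and [subsample_to_1hz()].
#'
#' @inheritParams static_acceleration
#' @return A `vedba_series`; the full-rate VeDBA is kept in attribute
#'   `vedba_full` and the dynamic heave (mg) in `dynamic_heave_mg`, for
#'   downstream flight segmentation.
#' @export
compute_vedba <- function(trace, window = 1) {
  st <- static_acceleration(trace, window)
  dyn <- dynamic_acceleration(trace, st)
  v <- vedba(dyn)
  out <- subsample_to_1hz(v, trace$time_s, trace$sampling_rate)
  attr(out, "vedba_full") <- v
  attr(out, "dynamic_heave_mg") <- 1000 * dyn$heave_g
  out
}
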