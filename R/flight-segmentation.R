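#' Classify flapping versus gliding from the dynamic heave axis
#'
#' Candidate gliding is any maximal run of samples whose absolute dynamic
#' heave stays below `threshold` (default 300 mg); runs shorter than
#' `min_glide` seconds -- less than one wingbeat, e.g. the brief
#' sub-threshold dwells at the oscillation's zero crossings -- are
#' relabeled flapping.  The threshold applies to the dynamic (gravity
#' removed) heave: raw heave carries about 1000 mg of gravity in level
#' flight, which would make a 300 mg rule unsatisfiable.
#'
#' @param heave_dynamic_mg numeric vector, dynamic heave in mg at the
#'   native sampling rate.
#' @param sampling_rate sampling frequency, Hz.
#' @param threshold flap/glide threshold on `abs(heave)`, mg.
#' @param min_glide minimum gliding-run duration, seconds (one wingbeat).
#' @return A `flight_states` object: list with `state` (factor per
#'   sample), `segments` (data frame `state`, `start_s`, `end_s`), and
#'   `sampling_rate`.  Segments tile the record exactly.
#' @export
classify_flap_glide <- function(heave_dynamic_mg, sampling_rate,
                                threshold = 300, min_glide = 0.2) {
  if (!length(heave_dynamic_mg)) stop("empty series")
  stop_if_not_scalar_pos(sampling_rate, "sampling_rate")
  stop_if_not_scalar_pos(threshold, "threshold")
  r <- rle(abs(heave_dynamic_mg) < threshold)
  min_len <- round(min_glide * sampling_rate)
  r$values[r$values & r$lengths < min_len] <- FALSE
  state_rle <- rle(inverse.rle(r))  # merge adjacent runs after relabeling
  ends <- cumsum(state_rle$lengths)
  starts <- c(1L, utils::head(ends, -1L) + 1L)
  segments <- data.frame(
    state = ifelse(state_rle$values, "glide", "flap"),
    start_s = (starts - 1L) / sampling_rate,
    end_s = ends / sampling_rate
  )
  state <- factor(ifelse(inverse.rle(state_rle), "glide", "flap"),
                  levels = c("flap", "glide"))
  structure(
    list(state = state, segments = segments, sampling_rate = sampling_rate),
    class = "flight_states"
  )
}

#' Fraction of the record spent gliding, by duration
#'
#' @param states a `flight_states` object.
#' @return Proportion of samples labeled glide.
#' @export
glide_time_share <- function(states) {
  stopifnot(inherits(states, "flight_states"))
  mean(states$state == "glide")
}

#' Merge heart rate, VeDBA and flight state into the 1 Hz session table
#'
#' One row per 1 Hz VeDBA timestamp; the heart rate is the 5 Hz series'
#' value at that exact timestamp and the state is the instantaneous
#' flap/glide label at that instant (not a majority vote over the
#' second).  Rows without a valid heart-rate sample are flagged missing.
#'
#' @param hr an `hr_series` (5 Hz grid).
#' @param vedba_1hz a `vedba_series` (1 Hz grid).
#' @param states a `flight_states` object covering the session.
#' @param meta list with `bird`, `date`, `flight_number`, `logger_shape`
#'   (`"cube"` or `"drop"`) and `wind_angle` (2 or 6, degrees).
#' @return A `merged_session` data frame: `time_s`, `hr_bpm`, `vedba_mg`,
#'   `state`, `hr_missing`, plus the session metadata columns.
#' @export
merge_streams <- function(hr, vedba_1hz, states, meta) {
  stopifnot(inherits(hr, "hr_series"), inherits(vedba_1hz, "vedba_series"),
            inherits(states, "flight_states"))
  if (!all(c("bird", "date", "flight_number", "logger_shape", "wind_angle")
           %in% names(meta))) {
    stop("meta must provide bird, date, flight_number, logger_shape, wind_angle")
  }
  if (!meta$logger_shape %in% c("cube", "drop")) {
    stop("logger_shape must be 'cube' or 'drop'")
  }
  if (!meta$wind_angle %in% c(2, 6)) stop("wind_angle must be 2 or 6 degrees")
  t <- vedba_1hz$time_s
  n_state <- length(states$state)
  state_end <- n_state / states$sampling_rate
  if (nrow(hr) && (min(t) > max(hr$time_s) || max(t) < min(hr$time_s))) {
    stop("heart-rate and VeDBA series do not overlap in time")
  }
  if (min(t) > state_end || max(t) < 0) {
    stop("flight-state and VeDBA series do not overlap in time")
  }
  hr_idx <- match(round(t * 5), round(hr$time_s * 5))
  hr_val <- ifelse(is.na(hr_idx), NA_real_, hr$hr_bpm[pmax(hr_idx, 1L)])
  st_idx <- pmin(pmax(round(t * states$sampling_rate) + 1L, 1L), n_state)
  structure(
    data.frame(
      time_s = t,
      hr_bpm = hr_val,
      vedba_mg = vedba_1hz$vedba_mg,
      state = as.character(states$state[st_idx]),
      hr_missing = is.na(hr_val),
      bird = meta$bird,
      date = meta$date,
      flight_number = meta$flight_number,
      logger_shape = meta$logger_shape,
      wind_angle = meta$wind_angle,
      stringsAsFactors = FALSE
    ),
    class = c("merged_session", "data.frame")
  )
}

#' Proportion of 1 Hz rows spent gliding in a merged session
#'
#' @param session a `merged_session`.
#' @return Fraction in [0, 1].
#' @export
gliding_proportion <- function(session) {
  stopifnot(inherits(session, "merged_session"), nrow(session) > 0L)
  mean(session$state == "glide")
}

#' Per-condition summary of merged sessions
#'
#' Summarizes a set of flight sessions by experimental condition (logger
#' shape x wind angle): number of flights, recorded seconds, mean heart
#' rate over non-missing rows, mean VeDBA, and the pooled gliding
#' proportion.
#'
#' @param sessions list of `merged_session` objects.
#' @return Data frame with one row per condition.
#' @export
condition_summary <- function(sessions) {
  df <- do.call(rbind, lapply(sessions, as.data.frame))
  if (!all(df$logger_shape %in% c("cube", "drop")) ||
      !all(df$wind_angle %in% c(2, 6))) {
    stop("unknown condition labels")
  }
  key <- interaction(df$logger_shape, df$wind_angle, drop = TRUE, sep = "|")
  out <- do.call(rbind, lapply(split(df, key), function(g) {
    data.frame(
      logger_shape = g$logger_shape[1],
      wind_angle = g$wind_angle[1],
      n_flights = nrow(unique(g[, c("bird", "date", "flight_number")])),
      seconds = nrow(g),
      mean_hr_bpm = mean(g$hr_bpm[!g$hr_missing]),
      mean_vedba_mg = mean(g$vedba_mg),
      gliding_prop = mean(g$state == "glide")
    )
  }))
  rownames(out) <- NULL
  out[order(out$logger_shape, out$wind_angle), ]
}

#' Heart rate and VeDBA summarized by flight mode
#'
#' Group means and standard deviations of heart rate and VeDBA for
#' flapping versus gliding rows across sessions.  A state absent from the
#' data is reported with NA, not zero.
#'
#' @param sessions list of `merged_session` objects.
#' @return Data frame with one row per state (`flap`, `glide`).
#' @export
flap_glide_summary <- function(sessions) {
  df <- do.call(rbind, lapply(sessions, as.data.frame))
  do.call(rbind, lapply(c("flap", "glide"), function(s) {
    g <- df[df$state == s, , drop = FALSE]
    if (!nrow(g)) {
      return(data.frame(state = s, n_seconds = 0L, mean_hr_bpm = NA_real_,
                        sd_hr_bpm = NA_real_, mean_vedba_mg = NA_real_,
                        sd_vedba_mg = NA_real_))
    }
    hr <- g$hr_bpm[!g$hr_missing]
    data.frame(
      state = s, n_seconds = nrow(g),
      mean_hr_bpm = if (length(hr)) mean(hr) else NA_real_,
      sd_hr_bpm = if (length(hr) > 1) stats::sd(hr) else NA_real_,
      mean_vedba_mg = mean(g$vedba_mg),
      sd_vedba_mg = stats::sd(g$vedba_mg)
    )
  }))
}
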