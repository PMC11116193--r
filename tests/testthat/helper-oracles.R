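# Independent brute-force oracles: deliberately naive implementations,
# kept separate from the package's code paths.

oracle_haversine_km <- function(lat1, lon1, lat2, lon2) {
  rad <- pi / 180
  a <- sin((lat2 - lat1) * rad / 2)^2 +
    cos(lat1 * rad) * cos(lat2 * rad) * sin((lon2 - lon1) * rad / 2)^2
  2 * 6371 * asin(sqrt(pmin(1, a)))
}

oracle_path_km <- function(lat, lon) {
  if (length(lat) < 2) return(0)
  s <- 0
  for (i in seq_len(length(lat) - 1)) {
    s <- s + oracle_haversine_km(lat[i], lon[i], lat[i + 1], lon[i + 1])
  }
  s
}

oracle_neighbor_counts <- function(time_s, hr_bpm, tw, hw) {
  n <- length(time_s)
  counts <- integer(n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i != j && abs(time_s[j] - time_s[i]) <= tw &&
          abs(hr_bpm[j] - hr_bpm[i]) <= hw) {
        counts[i] <- counts[i] + 1L
      }
    }
  }
  counts
}

oracle_runmean <- function(x, halfwidth) {
  n <- length(x)
  out <- numeric(n)
  for (i in seq_len(n)) {
    out[i] <- mean(x[max(1, i - halfwidth):min(n, i + halfwidth)])
  }
  out
}

oracle_vedba_mg <- function(dx, dy, dz) {
  out <- numeric(length(dx))
  for (i in seq_along(dx)) {
    out[i] <- 1000 * sqrt(dx[i]^2 + dy[i]^2 + dz[i]^2)
  }
  out
}

oracle_normal_equations <- function(X, y) {
  drop(solve(t(X) %*% X, t(X) %*% y))
}

# --- construction helpers for fixtures built in code ---------------------

make_beats <- function(time_s, hr_bpm) {
  structure(data.frame(time_s = time_s, hr_bpm = hr_bpm),
            class = c("beat_series", "data.frame"))
}

make_hr_series <- function(time_s, hr_bpm) {
  structure(
    data.frame(time_s = time_s, hr_bpm = hr_bpm,
               quality = ifelse(is.na(hr_bpm), "gap", "ok")),
    class = c("hr_series", "data.frame")
  )
}

make_vedba_series <- function(time_s, vedba_mg) {
  structure(data.frame(time_s = time_s, vedba_mg = vedba_mg),
            class = c("vedba_series", "data.frame"))
}

make_accel_trace <- function(heave_g, sampling_rate = 1600,
                             surge_g = rep(0, length(heave_g)),
                             sway_g = rep(0, length(heave_g))) {
  structure(
    list(time_s = (seq_along(heave_g) - 1) / sampling_rate,
         surge_g = surge_g, sway_g = sway_g, heave_g = heave_g,
         sampling_rate = sampling_rate, truth = NULL, metadata = list()),
    class = "accel_trace"
  )
}

make_session <- function(state, hr_bpm = 400, vedba_mg = 500, bird = "310",
                         date = as.Date("2020-08-01"), flight_number = 1,
                         logger_shape = "cube", wind_angle = 2) {
  n <- length(state)
  structure(
    data.frame(time_s = seq_len(n) - 1, hr_bpm = rep_len(hr_bpm, n),
               vedba_mg = rep_len(vedba_mg, n), state = state,
               hr_missing = is.na(rep_len(hr_bpm, n)), bird = bird,
               date = date, flight_number = flight_number,
               logger_shape = logger_shape, wind_angle = wind_angle,
               stringsAsFactors = FALSE),
    class = c("merged_session", "data.frame")
  )
}

make_daily_summary <- function(date, path_km, start_lat, end_lat,
                               lon = 11, bird = "b1") {
  structure(
    data.frame(bird = bird, date = date, path_km = path_km,
               day_type = ifelse(path_km >= 50, "migration", "stopover"),
               n_fixes = 10L, start_lat = start_lat, start_lon = lon,
               end_lat = end_lat, end_lon = lon, stringsAsFactors = FALSE),
    class = c("daily_summary", "data.frame")
  )
}

# A glide-only flight plan whose trace is quiet enough that the synthetic
# ECG carries no motion artifact (for clean heart-rate recovery tests).
quiet_plan <- function(duration_s, sampling_rate = 1600) {
  flight_plan(
    data.frame(state = "glide", duration_s = duration_s, amplitude_mg = 0),
    sampling_rate = sampling_rate
  )
}
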