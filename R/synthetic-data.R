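#' Describe a wind-tunnel flight as alternating flapping and gliding bouts
#'
#' A flight plan is the ground-truth script from which synthetic tri-axial
#' acceleration is generated: an ordered sequence of flight segments, each
#' either powered flapping (oscillatory heave at the wingbeat frequency,
#' dynamic amplitude above the 300 mg flap/glide threshold) or passive
#' gliding (dynamic heave well below it).
#'
#' @param segments data frame with columns `state` (`"flap"` or `"glide"`),
#'   `duration_s` (segment length, seconds), `amplitude_mg` (peak dynamic
#'   heave amplitude, milli-g) and optionally `wingbeat_hz` (oscillation
#'   frequency, default 5 Hz, the span of one ~0.2 s wingbeat).
#' @param sampling_rate sampling frequency in Hz (default 1600, the logger's
#'   native rate).
#' @return An object of class `flight_plan`.
#' @export
flight_plan <- function(segments, sampling_rate = 1600) {
  stopifnot(is.data.frame(segments), nrow(segments) >= 1L)
  stop_if_not_scalar_pos(sampling_rate, "sampling_rate")
  required <- c("state", "duration_s", "amplitude_mg")
  missing_cols <- setdiff(required, names(segments))
  if (length(missing_cols)) {
    stop("`segments` lacks columns: ", paste(missing_cols, collapse = ", "))
  }
  if (is.null(segments$wingbeat_hz)) segments$wingbeat_hz <- 5
  if (!all(segments$state %in% c("flap", "glide"))) {
    stop("segment states must be 'flap' or 'glide'")
  }
  if (any(segments$duration_s <= 0)) stop("segment durations must be positive")
  flap <- segments$state == "flap"
  if (any(segments$amplitude_mg[flap] <= 300)) {
    stop("flap segments must have dynamic heave amplitude > 300 mg")
  }
  if (any(segments$amplitude_mg[!flap] >= 300)) {
    stop("glide segments must have dynamic heave amplitude < 300 mg")
  }
  if (any(segments$amplitude_mg < 0)) stop("amplitudes must be non-negative")
  if (any(flap & segments$wingbeat_hz <= 0)) {
    stop("flap segments need a positive wingbeat frequency")
  }
  structure(
    list(segments = segments, sampling_rate = sampling_rate),
    class = "flight_plan"
  )
}

#' Generate a synthetic tri-axial acceleration trace from a flight plan
#'
#' Emulates a back-mounted accelerometer sampling at the logger's native
#' rate within its +/- 8 g range.  The heave (dorsoventral) axis carries a
#' ~1 g static gravity component -- optionally tilted by a slow sinusoidal
#' orientation drift so the running-mean static estimate is non-trivially
#' exercised -- plus a per-segment wingbeat oscillation and white sensor
#' noise.  Surge and sway carry attenuated copies of the wingbeat
#' oscillation.  The latent per-sample flap/glide state and the clean
#' dynamic heave are returned as ground truth.
#'
#' @param plan a [flight_plan()].
#' @param seed integer seed; identical seeds give bit-identical traces.
#' @param noise_sd_g white-noise standard deviation per axis, in g.
#' @param drift_deg amplitude of the slow gravity-tilt drift, degrees
#'   (0 disables drift).
#' @param drift_hz frequency of the orientation drift (must stay below the
#'   static-estimation window's passband, default 0.1 Hz).
#' @return An object of class `accel_trace`: list with `time_s`, `surge_g`,
#'   `sway_g`, `heave_g`, `sampling_rate`, `metadata`, and a `truth` list
#'   carrying `state` (factor, per sample) and `dynamic_heave_g`.
#' @export
generate_accel <- function(plan, seed = NULL, noise_sd_g = 0.02,
                           drift_deg = 10, drift_hz = 0.1) {
  stopifnot(inherits(plan, "flight_plan"))
  fs <- plan$sampling_rate
  seg <- plan$segments
  if (any(1 + seg$amplitude_mg / 1000 + 5 * noise_sd_g > 8)) {
    stop("requested amplitude would exceed the +/- 8 g logger range")
  }
  n_per <- round(seg$duration_s * fs)
  if (any(n_per < 1)) stop("segment shorter than one sample at this rate")
  n <- sum(n_per)
  state <- factor(rep(seg$state, n_per), levels = c("flap", "glide"))
  amp_g <- rep(seg$amplitude_mg, n_per) / 1000
  freq <- rep(seg$wingbeat_hz, n_per)
  # per-segment local time so each bout's oscillation starts at phase zero
  t_local <- (unlist(lapply(n_per, seq_len), use.names = FALSE) - 1) / fs
  time_s <- (seq_len(n) - 1) / fs

  with_seed(seed, {
    osc <- amp_g * sin(2 * pi * freq * t_local)
    theta <- if (drift_deg > 0) {
      (drift_deg * pi / 180) * sin(2 * pi * drift_hz * time_s +
                                     stats::runif(1, 0, 2 * pi))
    } else {
      rep(0, n)
    }
    noise <- function() {
      if (noise_sd_g > 0) stats::rnorm(n, 0, noise_sd_g) else rep(0, n)
    }
    heave <- cos(theta) + osc + noise()
    surge <- sin(theta) + 0.30 * amp_g * sin(2 * pi * freq * t_local + pi / 2) +
      noise()
    sway <- 0.15 * amp_g * sin(2 * pi * freq * t_local + pi / 3) + noise()
    structure(
      list(
        time_s = time_s,
        surge_g = pmin(pmax(surge, -8), 8),
        sway_g = pmin(pmax(sway, -8), 8),
        heave_g = pmin(pmax(heave, -8), 8),
        sampling_rate = fs,
        truth = list(state = state, dynamic_heave_g = osc),
        metadata = list()
      ),
      class = "accel_trace"
    )
  })
}

#' Describe a heart-rate trajectory and ECG morphology
#'
#' @param breakpoints data frame with columns `time_s` and `hr_bpm`; the
#'   instantaneous heart rate follows linear interpolation between
#'   breakpoints (held constant beyond the ends).
#' @param qrs_width_s nominal QRS-complex width in seconds (Gaussian pulse;
#'   the pulse's standard deviation is half this value).
#' @param qrs_amplitude_mV R-peak amplitude in mV; must sit inside the
#'   logger's +/- 6 mV range together with the baseline wander.
#' @param noise_sd_mV white sensor-noise standard deviation, mV.
#' @param artifact_gain_mV_per_g motion-artifact gain: mV of additive ECG
#'   artifact per g of dynamic heave (activity corrupts the electrode
#'   signal, mirroring real flapping flight).
#' @param wander_amplitude_mV,wander_hz baseline-wander sinusoid.
#' @return An object of class `hr_profile`.
#' @export
hr_profile <- function(breakpoints, qrs_width_s = 0.008, qrs_amplitude_mV = 4,
                       noise_sd_mV = 0.05, artifact_gain_mV_per_g = 0.5,
                       wander_amplitude_mV = 0.3, wander_hz = 0.25) {
  stopifnot(is.data.frame(breakpoints),
            all(c("time_s", "hr_bpm") %in% names(breakpoints)),
            nrow(breakpoints) >= 1L)
  if (any(breakpoints$hr_bpm <= 60 | breakpoints$hr_bpm >= 800)) {
    stop("heart rate breakpoints must lie in (60, 800) bpm")
  }
  if (is.unsorted(breakpoints$time_s, strictly = nrow(breakpoints) > 1L)) {
    stop("breakpoint times must be strictly increasing")
  }
  stop_if_not_scalar_pos(qrs_width_s, "qrs_width_s")
  if (abs(qrs_amplitude_mV) + wander_amplitude_mV > 6) {
    stop("QRS amplitude plus baseline wander exceeds the +/- 6 mV range")
  }
  structure(
    list(
      breakpoints = breakpoints, qrs_width_s = qrs_width_s,
      qrs_amplitude_mV = qrs_amplitude_mV, noise_sd_mV = noise_sd_mV,
      artifact_gain_mV_per_g = artifact_gain_mV_per_g,
      wander_amplitude_mV = wander_amplitude_mV, wander_hz = wander_hz
    ),
    class = "hr_profile"
  )
}

#' Generate a synthetic ECG trace synchronized with an acceleration trace
#'
#' Places Gaussian-shaped QRS pulses at R-times whose instantaneous rate
#' follows the profile's breakpoints (beat times are the integer crossings
#' of the integrated beat phase), then adds baseline wander, white noise
#' and a motion artifact proportional to the trace's clean dynamic heave.
#' Samples are clipped to the logger's +/- 6 mV range.  The true R-times
#' are returned as ground truth.
#'
#' @param profile an [hr_profile()].
#' @param accel an `accel_trace` from [generate_accel()]; defines the
#'   sampling rate, duration and the dynamic heave driving the artifact.
#' @param seed integer seed for the stochastic components.
#' @return An object of class `ecg_trace`: list with `time_s`, `ecg_mV`,
#'   `sampling_rate`, `metadata`, and `truth$r_times` (seconds).
#' @export
generate_ecg <- function(profile, accel, seed = NULL) {
  stopifnot(inherits(profile, "hr_profile"), inherits(accel, "accel_trace"))
  fs <- accel$sampling_rate
  t <- accel$time_s
  n <- length(t)
  bp <- profile$breakpoints
  rate <- if (nrow(bp) == 1L) {
    rep(bp$hr_bpm, n)
  } else {
    stats::approx(bp$time_s, bp$hr_bpm, xout = t, rule = 2)$y
  }
  if (any(60 / rate < 3 * profile$qrs_width_s)) {
    stop("RR interval shorter than 3 x QRS width: beats unresolvable")
  }
  # beat phase: integral of the instantaneous rate; beats at integer crossings
  phase <- cumsum(rate / 60) / fs
  n_beats <- floor(phase[n])
  if (n_beats < 1L) stop("trace too short to contain a single beat")
  r_times <- stats::approx(phase, t, xout = seq_len(n_beats))$y

  sd_q <- profile$qrs_width_s / 2
  v <- numeric(n)
  half <- ceiling(6 * sd_q * fs)
  for (tk in r_times) {
    ic <- round(tk * fs) + 1
    idx <- max(1, ic - half):min(n, ic + half)
    v[idx] <- v[idx] +
      profile$qrs_amplitude_mV * exp(-((t[idx] - tk)^2) / (2 * sd_q^2))
  }
  with_seed(seed, {
    if (profile$wander_amplitude_mV > 0) {
      v <- v + profile$wander_amplitude_mV *
        sin(2 * pi * profile$wander_hz * t + stats::runif(1, 0, 2 * pi))
    }
    if (profile$noise_sd_mV > 0) v <- v + stats::rnorm(n, 0, profile$noise_sd_mV)
    v <- v + profile$artifact_gain_mV_per_g * accel$truth$dynamic_heave_g
    structure(
      list(
        time_s = t,
        ecg_mV = pmin(pmax(v, -6), 6),
        sampling_rate = fs,
        truth = list(r_times = r_times),
        metadata = accel$metadata
      ),
      class = "ecg_trace"
    )
  })
}

#' Describe a multi-day migration itinerary
#'
#' @param days data frame with columns `date` (`Date`), `target_km`
#'   (connected daily path length to generate) and `day_type`
#'   (`"migration"` or `"stopover"`); an optional `bearing_offset_deg`
#'   column rotates a migration day's heading away from the breeding-site
#'   bearing (0 = straight toward it; 180 makes a direction-violating
#'   decoy).  Migration days must target at least 50 km, stopover days
#'   less than 50 km (they are generated as out-and-back foraging loops
#'   with near-zero net displacement).
#' @param start `c(lat, lon)` of the itinerary's first fix (WGS84 degrees).
#' @param breeding_site `c(lat, lon)` migration destination.
#' @param fixes_per_day number of GPS fixes emitted per day (>= 2).
#' @param bird individual identifier.
#' @param attachment harness type, `"leg_loop"` or `"wing_loop"`.
#' @param jitter_m per-fix isotropic position jitter, metres.
#' @return An object of class `itinerary`.
#' @export
itinerary <- function(days, start, breeding_site, fixes_per_day = 60,
                      bird = "bird01", attachment = c("leg_loop", "wing_loop"),
                      jitter_m = 15) {
  stopifnot(is.data.frame(days),
            all(c("date", "target_km", "day_type") %in% names(days)),
            length(start) == 2L, length(breeding_site) == 2L)
  attachment <- match.arg(attachment)
  if (!all(days$day_type %in% c("migration", "stopover"))) {
    stop("day_type must be 'migration' or 'stopover'")
  }
  if (any(days$target_km < 0)) stop("targets must be non-negative")
  mig <- days$day_type == "migration"
  if (any(days$target_km[mig] < 50)) {
    stop("migration days must target at least 50 km")
  }
  if (any(days$target_km[!mig] >= 50)) {
    stop("stopover days must target less than 50 km")
  }
  if (fixes_per_day < 2) stop("fixes_per_day must be at least 2")
  if (any(abs(c(start[1], breeding_site[1])) > 90) ||
      any(abs(c(start[2], breeding_site[2])) > 180)) {
    stop("invalid coordinates")
  }
  if (is.null(days$bearing_offset_deg)) days$bearing_offset_deg <- 0
  structure(
    list(
      days = days, start = start, breeding_site = breeding_site,
      fixes_per_day = fixes_per_day, bird = bird, attachment = attachment,
      jitter_m = jitter_m
    ),
    class = "itinerary"
  )
}

#' Generate a synthetic GPS track from an itinerary
#'
#' Migration days trace a single great-circle leg from the bird's current
#' position toward the breeding site (optionally rotated by the day's
#' bearing offset) with equally spaced fixes summing to the day's target
#' path length; stopover days are out-and-back foraging loops along a
#' random bearing returning to the day's start.  Each fix receives
#' isotropic position jitter that is negligible at the 50 km scale, so
#' connected daily path lengths recover the targets within 1%.
#'
#' @param it an [itinerary()].
#' @param seed integer seed.
#' @return An object of class `gps_track`: data frame with `timestamp`
#'   (POSIXct UTC), `lat`, `lon`, `bird`; attributes `attachment` and
#'   `truth` (the itinerary's day table).
#' @export
generate_gps_track <- function(it, seed = NULL) {
  stopifnot(inherits(it, "itinerary"))
  n_fix <- it$fixes_per_day
  if (any(it$days$target_km > 0) && n_fix < 2) {
    stop("non-zero targets unreachable with fewer than 2 fixes per day")
  }
  with_seed(seed, {
    cur <- c(it$start[2], it$start[1])  # geosphere wants (lon, lat)
    dest <- c(it$breeding_site[2], it$breeding_site[1])
    rows <- vector("list", nrow(it$days))
    for (d in seq_len(nrow(it$days))) {
      day <- it$days[d, ]
      target_m <- day$target_km * 1000
      if (target_m == 0) {
        dist_along <- rep(0, n_fix)
        brg <- 0
      } else if (day$day_type == "migration") {
        brg <- geosphere::bearing(cur, dest) + day$bearing_offset_deg
        dist_along <- seq(0, target_m, length.out = n_fix)
      } else {
        if (n_fix < 3) stop("stopover loops need at least 3 fixes per day")
        brg <- stats::runif(1, 0, 360)
        half <- target_m / 2
        k <- seq_len(n_fix) - 1
        h <- floor((n_fix - 1) / 2)
        out <- pmin(k, h) * (half / h)
        back <- pmax(k - h, 0) * (half / (n_fix - 1 - h))
        dist_along <- out - back
      }
      pts <- geosphere::destPoint(cur, brg, dist_along, r = 6371000)
      if (it$jitter_m > 0) {
        pts[, 2] <- pts[, 2] + stats::rnorm(n_fix, 0, it$jitter_m / 111320)
        pts[, 1] <- pts[, 1] + stats::rnorm(n_fix, 0, it$jitter_m /
                                              (111320 * cos(pts[, 2] * pi / 180)))
      }
      t0 <- as.POSIXct(paste(day$date, "06:00:00"), tz = "UTC")
      rows[[d]] <- data.frame(
        timestamp = t0 + (seq_len(n_fix) - 1) * (10 * 3600) / (n_fix - 1),
        lat = pts[, 2], lon = pts[, 1], bird = it$bird,
        stringsAsFactors = FALSE
      )
      if (day$day_type == "migration" && target_m > 0) {
        cur <- geosphere::destPoint(cur, brg, target_m, r = 6371000)[1, ]
      }
    }
    track <- do.call(rbind, rows)
    structure(track, attachment = it$attachment, truth = it$days,
              class = c("gps_track", "data.frame"))
  })
}
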