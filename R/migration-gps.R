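#' Great-circle path length of an ordered sequence of GPS fixes
#'
#' Sum of haversine distances between consecutive fixes on a sphere of
#' mean radius 6371 km; a single fix has length zero.
#'
#' @param lat,lon numeric vectors of WGS84 coordinates in degrees.
#' @return Path length in km.
#' @export
path_length <- function(lat, lon) {
  stopifnot(length(lat) == length(lon), length(lat) >= 1L)
  if (any(abs(lat) > 90) || any(abs(lon) > 180) || anyNA(lat) || anyNA(lon)) {
    stop("invalid coordinates")
  }
  n <- length(lat)
  if (n == 1L) return(0)
  p <- cbind(lon, lat)
  sum(geosphere::distHaversine(p[-n, , drop = FALSE], p[-1, , drop = FALSE],
                               r = 6371000)) / 1000
}

#' Daily flight distances and migration/stopover classification
#'
#' Buckets fixes by civil date in `tz` (default Europe/Rome, a single
#' zone covering the Italy-Austria-Germany corridor), computes each day's
#' connected path length over that day's fixes only (segments spanning
#' midnight are not credited to either day; their count is reported in
#' attribute `n_dropped_segments`), and classifies each day as migration
#' when the path reaches `threshold_km` (inclusive) and stopover
#' otherwise.
#'
#' @param track a `gps_track` (data frame with `timestamp`, `lat`, `lon`,
#'   `bird`; see [generate_gps_track()] and [read_gps_csv()]).
#' @param tz time zone defining the day boundary.
#' @param threshold_km minimum daily travel distance for a migration day.
#' @return A `daily_summary` data frame: `bird`, `date`, `path_km`,
#'   `day_type`, `n_fixes`, the day's first/last fix coordinates, and
#'   `attachment` (carried over from the track when present).
#' @export
daily_distances <- function(track, tz = "Europe/Rome", threshold_km = 50) {
  stopifnot(is.data.frame(track), nrow(track) >= 1L,
            all(c("timestamp", "lat", "lon") %in% names(track)))
  if (is.unsorted(as.numeric(track$timestamp))) {
    stop("timestamps must be non-decreasing")
  }
  date <- as.Date(format(track$timestamp, tz = tz))
  n_dropped <- sum(date[-1] != date[-length(date)])
  out <- do.call(rbind, lapply(split(seq_len(nrow(track)), date), function(i) {
    g <- track[i, , drop = FALSE]
    len <- path_length(g$lat, g$lon)
    data.frame(
      bird = if (!is.null(g$bird)) g$bird[1] else NA_character_,
      date = as.Date(format(g$timestamp[1], tz = tz)),
      path_km = len,
      day_type = if (len >= threshold_km) "migration" else "stopover",
      n_fixes = nrow(g),
      start_lat = g$lat[1], start_lon = g$lon[1],
      end_lat = g$lat[nrow(g)], end_lon = g$lon[nrow(g)],
      stringsAsFactors = FALSE
    )
  }))
  rownames(out) <- NULL
  out <- out[order(out$date), ]
  attr(out, "attachment") <- attr(track, "attachment")
  attr(out, "n_dropped_segments") <- n_dropped
  class(out) <- c("daily_summary", "data.frame")
  out
}

#' Migration start date from daily summaries
#'
#' The start of migration is the first day such that it and the following
#' calendar day both cover at least `threshold_km` and both head toward
#' the breeding site: the day's net-displacement bearing (first to last
#' fix) lies within +/- 90 degrees of the great-circle bearing from the
#' day's start to the breeding site.
#'
#' @param daily a `daily_summary` for one bird, date-ordered.
#' @param breeding_site `c(lat, lon)` of the breeding site.
#' @param threshold_km minimum daily distance (default 50 km).
#' @return The start `Date`, or `NA` if no qualifying pair of days exists.
#' @export
migration_start <- function(daily, breeding_site, threshold_km = 50) {
  stopifnot(inherits(daily, "daily_summary"), length(breeding_site) == 2L)
  if (nrow(daily) < 2L) return(as.Date(NA))
  start_p <- cbind(daily$start_lon, daily$start_lat)
  end_p <- cbind(daily$end_lon, daily$end_lat)
  net_brg <- geosphere::bearing(start_p, end_p)
  to_breeding <- geosphere::bearing(start_p,
                                    cbind(breeding_site[2], breeding_site[1]))
  net_m <- geosphere::distHaversine(start_p, end_p, r = 6371000)
  qualifies <- daily$path_km >= threshold_km &
    net_m > 1 &  # a loop day has no meaningful heading
    abs(angle_diff(net_brg, to_breeding)) <= 90
  for (d in seq_len(nrow(daily) - 1L)) {
    if (qualifies[d] && qualifies[d + 1L] &&
        daily$date[d + 1L] == daily$date[d] + 1L) {
      return(daily$date[d])
    }
  }
  as.Date(NA)
}

#' Relative increase of one mean daily distance over another, in percent
#'
#' With distance covered per day `a` (e.g. leg-loop birds) versus `b`
#' (e.g. wing-loop birds), a journey of fixed length takes `a / b` times
#' fewer days under `a`; the value returned, `100 * (a - b) / b`, is the
#' percentage by which daily progress -- and hence the reduction in total
#' migration duration -- differs between the groups.
#'
#' @param mean_daily_a,mean_daily_b mean daily distances in km (> 0).
#' @return Percentage difference.
#' @export
duration_reduction <- function(mean_daily_a, mean_daily_b) {
  stop_if_not_scalar_pos(mean_daily_a, "mean_daily_a")
  stop_if_not_scalar_pos(mean_daily_b, "mean_daily_b")
  100 * (mean_daily_a - mean_daily_b) / mean_daily_b
}
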