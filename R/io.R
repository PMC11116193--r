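#' Read and write the pipeline's CSV interchange formats
#'
#' Plain-text formats used to exchange data with loggers and downstream
#' tools: time-series CSVs for ECG (`time_s`, `ecg_mV`) and acceleration
#' (`time_s`, `ax_g`, `ay_g`, `az_g`; surge, sway, heave), a
#' Movebank-style GPS CSV (`timestamp` ISO-8601 UTC, `location-lat`,
#' `location-long`, `individual-local-identifier`), and writers for the
#' processed 5 Hz heart-rate, 1 Hz VeDBA, merged-session and
#' daily-summary tables.
#'
#' @param path file path.
#' @param sampling_rate sampling rate in Hz for the time-series readers.
#' @param x object to write.
#' @name pipeline_io
NULL

#' @rdname pipeline_io
#' @export
read_ecg_csv <- function(path, sampling_rate = 1600) {
  d <- utils::read.csv(path, check.names = FALSE)
  stopifnot(all(c("time_s", "ecg_mV") %in% names(d)))
  structure(
    list(time_s = d$time_s, ecg_mV = d$ecg_mV, sampling_rate = sampling_rate,
         truth = NULL, metadata = list(path = path)),
    class = "ecg_trace"
  )
}

#' @rdname pipeline_io
#' @export
write_ecg_csv <- function(x, path) {
  stopifnot(inherits(x, "ecg_trace"))
  utils::write.csv(data.frame(time_s = x$time_s, ecg_mV = x$ecg_mV), path,
                   row.names = FALSE)
  invisible(path)
}

#' @rdname pipeline_io
#' @export
read_accel_csv <- function(path, sampling_rate = 1600) {
  d <- utils::read.csv(path, check.names = FALSE)
  stopifnot(all(c("time_s", "ax_g", "ay_g", "az_g") %in% names(d)))
  structure(
    list(time_s = d$time_s, surge_g = d$ax_g, sway_g = d$ay_g,
         heave_g = d$az_g, sampling_rate = sampling_rate, truth = NULL,
         metadata = list(path = path)),
    class = "accel_trace"
  )
}

#' @rdname pipeline_io
#' @export
write_accel_csv <- function(x, path) {
  stopifnot(inherits(x, "accel_trace"))
  utils::write.csv(
    data.frame(time_s = x$time_s, ax_g = x$surge_g, ay_g = x$sway_g,
               az_g = x$heave_g),
    path, row.names = FALSE
  )
  invisible(path)
}

#' @rdname pipeline_io
#' @export
read_gps_csv <- function(path) {
  d <- utils::read.csv(path, check.names = FALSE)
  need <- c("timestamp", "location-lat", "location-long",
            "individual-local-identifier")
  stopifnot(all(need %in% names(d)))
  structure(
    data.frame(
      timestamp = as.POSIXct(d$timestamp, tz = "UTC",
                             format = "%Y-%m-%dT%H:%M:%OSZ"),
      lat = d[["location-lat"]],
      lon = d[["location-long"]],
      bird = d[["individual-local-identifier"]],
      stringsAsFactors = FALSE
    ),
    class = c("gps_track", "data.frame")
  )
}

#' @rdname pipeline_io
#' @export
write_gps_csv <- function(x, path) {
  stopifnot(all(c("timestamp", "lat", "lon", "bird") %in% names(x)))
  out <- data.frame(
    timestamp = format(x$timestamp, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC"),
    check.names = FALSE
  )
  out[["location-lat"]] <- x$lat
  out[["location-long"]] <- x$lon
  out[["individual-local-identifier"]] <- x$bird
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' @rdname pipeline_io
#' @export
write_table_csv <- function(x, path) {
  utils::write.csv(as.data.frame(x), path, row.names = FALSE)
  invisible(path)
}
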