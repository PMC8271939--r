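#' Construct a sensor time series
#'
#' A light container for a single wearable channel: a strictly increasing
#' time base in seconds from session start and one finite-valued signal
#' (heart rate in bpm, or trunk pitch in degrees from vertical).
#'
#' @param time Numeric vector of timestamps in seconds, strictly increasing.
#' @param values Numeric vector of signal values, same length as `time`.
#' @param nominal_rate Nominal sampling rate in Hz (e.g. 1 for a chest-strap
#'   heart-rate stream, 100 for an IMU pitch stream).
#' @param units Character label for the signal units (informational).
#'
#' @return An object of class `sensor_series`: a list with elements `time`,
#'   `values`, `nominal_rate` and `units`.
#' @examples
#' hr <- sensor_series(0:9, rep(60, 10), nominal_rate = 1, units = "bpm")
#' hr
#' @export
sensor_series <- function(time, values, nominal_rate, units = "") {
  time <- as.numeric(time)
  values <- as.numeric(values)
  if (length(time) == 0L) {
    stop("sensor_series: empty series", call. = FALSE)
  }
  if (length(time) != length(values)) {
    stop("sensor_series: 'time' and 'values' must have equal length", call. = FALSE)
  }
  if (anyNA(time) || any(!is.finite(time))) {
    stop("sensor_series: non-finite timestamps", call. = FALSE)
  }
  if (anyNA(values) || any(!is.finite(values))) {
    stop("sensor_series: non-finite signal values", call. = FALSE)
  }
  if (length(time) > 1L && any(diff(time) <= 0)) {
    stop("sensor_series: timestamps must be strictly increasing", call. = FALSE)
  }
  if (!is.numeric(nominal_rate) || length(nominal_rate) != 1L || nominal_rate <= 0) {
    stop("sensor_series: 'nominal_rate' must be a single positive number", call. = FALSE)
  }
  structure(
    list(time = time, values = values,
         nominal_rate = as.numeric(nominal_rate), units = as.character(units)),
    class = "sensor_series"
  )
}

#' @export
print.sensor_series <- function(x, ...) {
  cat(sprintf("<sensor_series> %d samples, %.6g-%.6g s, nominal %g Hz%s\n",
              length(x$time), x$time[1L], x$time[length(x$time)],
              x$nominal_rate,
              if (nzchar(x$units)) paste0(" [", x$units, "]") else ""))
  invisible(x)
}

#' @export
length.sensor_series <- function(x) length(x$time)

# span covered by the series, as c(first, last) timestamps
series_span <- function(x) c(x$time[1L], x$time[length(x$time)])

# values at samples with time in [from, to); empty window allowed
window_values <- function(x, from, to) {
  x$values[x$time >= from & x$time < to]
}
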