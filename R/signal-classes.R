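#' Construct a marker trajectory
#'
#' A marker trajectory is a tibble with columns `time` (seconds), `x`
#' (anterior-posterior), `y` (mediolateral) and `z` (vertical), all positions
#' in meters, sampled uniformly. Sampling rate and subject identity travel as
#' attributes so the object still behaves as an ordinary tibble in pipelines.
#'
#' @param positions data frame with numeric columns `x`, `y`, `z` in meters
#'   (a `time` column is recomputed from `rate` if absent). `NA` entries mark
#'   marker dropouts to be handled by [fill_marker_gaps()].
#' @param rate sampling rate in Hz (60 for camera-based capture).
#' @param subject_id optional subject identifier.
#' @return a `marker_trajectory` tibble.
#' @seealso [derive_acceleration()], [read_marker_csv()]
#' @export
marker_trajectory <- function(positions, rate, subject_id = NA_character_) {
  check_number(rate, "rate", min = 0, strict_min = TRUE)
  positions <- tibble::as_tibble(positions)
  missing_cols <- setdiff(c("x", "y", "z"), names(positions))
  if (length(missing_cols) > 0) {
    abort(sprintf("trajectory is missing column(s): %s",
                  paste(missing_cols, collapse = ", ")),
          class = "gaitdx_format_error")
  }
  if (nrow(positions) < 3) {
    abort("a marker trajectory needs at least 3 samples.",
          class = "gaitdx_insufficient_data_error")
  }
  out <- tibble::tibble(
    time = (seq_len(nrow(positions)) - 1) / rate,
    x = as.numeric(positions$x),
    y = as.numeric(positions$y),
    z = as.numeric(positions$z)
  )
  structure(out,
            class = c("marker_trajectory", class(out)),
            rate = rate, subject_id = subject_id)
}

#' Construct an acceleration signal
#'
#' A 3-axis acceleration series in m/s^2 tagged with its source modality:
#' `"wearable"` for accelerometer exports, `"marker-derived"` for signals
#' obtained by double differencing a marker trajectory.
#'
#' @param accel data frame with numeric columns `x`, `y`, `z` in m/s^2.
#' @param rate sampling rate in Hz.
#' @param source `"wearable"` or `"marker-derived"`.
#' @param subject_id optional subject identifier.
#' @param t0 time of the first sample in seconds.
#' @return an `accel_signal` tibble with columns `time`, `x`, `y`, `z`.
#' @export
accel_signal <- function(accel, rate, source = c("wearable", "marker-derived"),
                         subject_id = NA_character_, t0 = 0) {
  check_number(rate, "rate", min = 0, strict_min = TRUE)
  source <- match.arg(source)
  accel <- tibble::as_tibble(accel)
  missing_cols <- setdiff(c("x", "y", "z"), names(accel))
  if (length(missing_cols) > 0) {
    abort(sprintf("acceleration table is missing column(s): %s",
                  paste(missing_cols, collapse = ", ")),
          class = "gaitdx_format_error")
  }
  if (nrow(accel) < 1) {
    abort("acceleration signal is empty.",
          class = "gaitdx_insufficient_data_error")
  }
  out <- tibble::tibble(
    time = t0 + (seq_len(nrow(accel)) - 1) / rate,
    x = as.numeric(accel$x),
    y = as.numeric(accel$y),
    z = as.numeric(accel$z)
  )
  structure(out,
            class = c("accel_signal", class(out)),
            rate = rate, source = source, subject_id = subject_id)
}

#' Sampling rate of a signal object
#' @param x a `marker_trajectory` or `accel_signal`.
#' @return rate in Hz.
#' @export
signal_rate <- function(x) attr(x, "rate")

#' Source modality of an acceleration signal
#' @param x an `accel_signal`.
#' @return `"wearable"` or `"marker-derived"`.
#' @export
signal_source <- function(x) attr(x, "source")

#' Subject id carried by a signal object
#' @param x a signal object.
#' @return subject identifier string.
#' @export
signal_subject <- function(x) attr(x, "subject_id")

#' @export
print.marker_trajectory <- function(x, ...) {
  cat(sprintf("<marker_trajectory> subject=%s, %d samples @ %g Hz (%.1f s)\n",
              signal_subject(x), nrow(x), signal_rate(x),
              nrow(x) / signal_rate(x)))
  NextMethod()
}

#' @export
print.accel_signal <- function(x, ...) {
  cat(sprintf("<accel_signal: %s> subject=%s, %d samples @ %g Hz (%.1f s)\n",
              signal_source(x), signal_subject(x), nrow(x), signal_rate(x),
              nrow(x) / signal_rate(x)))
  NextMethod()
}
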