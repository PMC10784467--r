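#' Fill short marker dropouts
#'
#' Camera-based capture loses markers for a few frames at a time; dropped
#' samples are `NA` in the position columns. Interior gaps of at most
#' `max_gap` samples are filled by per-axis linear interpolation. Longer
#' gaps cannot be interpolated safely: the trajectory is split there and a
#' `segment` column marks the independently processable pieces. Leading and
#' trailing invalid samples are trimmed.
#'
#' @param traj a [marker_trajectory()]; `NA`s mark dropouts.
#' @param max_gap largest interior gap (in samples) filled by interpolation.
#'   Default 6 (0.1 s at 60 Hz), a typical brief occlusion.
#' @return the trajectory with gaps filled and a `segment` integer column.
#' @export
fill_marker_gaps <- function(traj, max_gap = 6) {
  check_number(max_gap, "max_gap", min = 0)
  valid <- stats::complete.cases(tibble::as_tibble(traj)[c("x", "y", "z")])
  if (!any(valid)) {
    abort("all samples are invalid; trajectory is unusable.",
          class = "gaitdx_unusable_signal_error")
  }
  keep <- seq(which(valid)[1], tail(which(valid), 1))
  df <- tibble::as_tibble(traj)[keep, ]
  valid <- valid[keep]

  runs <- rle(valid)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1
  segment <- integer(nrow(df))
  seg_id <- 1L
  cursor_valid_start <- 1L
  for (k in seq_along(runs$lengths)) {
    if (runs$values[k]) {
      segment[starts[k]:ends[k]] <- seg_id
    } else if (runs$lengths[k] > max_gap) {
      seg_id <- seg_id + 1L           # unfillable gap: start a new segment
      segment[starts[k]:ends[k]] <- NA_integer_
    } else {
      segment[starts[k]:ends[k]] <- seg_id
      for (axis in c("x", "y", "z")) { # linear interpolation across the gap
        lo <- starts[k] - 1L
        hi <- ends[k] + 1L
        w <- (seq(starts[k], ends[k]) - lo) / (hi - lo)
        df[[axis]][starts[k]:ends[k]] <-
          (1 - w) * df[[axis]][lo] + w * df[[axis]][hi]
      }
    }
  }

  df$segment <- segment
  df <- df[!is.na(df$segment), ]
  out <- marker_trajectory(df[c("x", "y", "z")], rate = signal_rate(traj),
                           subject_id = signal_subject(traj))
  out$time <- df$time
  out$segment <- df$segment
  out
}

#' Derive acceleration from a marker trajectory
#'
#' Implements the successive-finite-difference derivation: displacement
#' between consecutive samples over the sample interval gives velocity, and
#' the same operation on velocity gives acceleration. The two passes combine
#' to the central second difference
#' `a[i] = (p[i+2] - 2 p[i+1] + p[i]) * rate^2`, exact on quadratic motion.
#' The output is two samples shorter than the input and its timestamps are
#' aligned to the centre sample of each triplet.
#'
#' @param traj a [marker_trajectory()]. If it carries multiple `segment`s
#'   (see [fill_marker_gaps()]) each segment is differentiated independently
#'   and a list of signals is returned.
#' @return an [accel_signal()] tagged `"marker-derived"` (or a list of them,
#'   one per segment).
#' @export
derive_acceleration <- function(traj) {
  if (!is.null(traj[["segment"]]) && length(unique(traj$segment)) > 1) {
    segs <- split(tibble::as_tibble(traj), traj$segment)
    return(purrr::map(segs, function(s) {
      derive_acceleration(marker_trajectory(s[c("x", "y", "z")],
                                            rate = signal_rate(traj),
                                            subject_id = signal_subject(traj)))
    }))
  }
  n <- nrow(traj)
  if (n < 3) {
    abort("need at least 3 samples to double-difference.",
          class = "gaitdx_insufficient_data_error")
  }
  rate <- signal_rate(traj)
  second_diff <- function(p) (p[3:n] - 2 * p[2:(n - 1)] + p[1:(n - 2)]) * rate^2
  accel_signal(
    tibble::tibble(x = second_diff(traj$x),
                   y = second_diff(traj$y),
                   z = second_diff(traj$z)),
    rate = rate, source = "marker-derived",
    subject_id = signal_subject(traj),
    t0 = traj$time[2]
  )
}

#' Zero-phase Butterworth low-pass filter
#'
#' Applies a digital Butterworth low-pass design forward and backward
#' (zero phase, so gait-event timing is not lagged). The effective amplitude
#' response is the squared magnitude of the one-pass design: a tone at the
#' cutoff comes out at amplitude ~0.5, not the one-pass -3 dB value. The
#' signal is padded by reflection (1 s, or the signal length if shorter)
#' before filtering to suppress edge transients on short walking bouts.
#'
#' @param sig an [accel_signal()].
#' @param order filter order (default 4).
#' @param cutoff_hz cutoff frequency in Hz (default 15); must be below the
#'   Nyquist frequency.
#' @return the filtered signal, same length and timestamps.
#' @export
butterworth_lowpass <- function(sig, order = 4, cutoff_hz = 15) {
  rate <- signal_rate(sig)
  check_number(order, "order", min = 1)
  if (!is.numeric(cutoff_hz) || cutoff_hz <= 0 || cutoff_hz >= rate / 2) {
    abort(sprintf("cutoff_hz = %g must lie in (0, Nyquist = %g).",
                  cutoff_hz, rate / 2),
          class = "gaitdx_parameter_error")
  }
  bf <- signal::butter(order, cutoff_hz / (rate / 2), type = "low")
  n <- nrow(sig)
  pad <- min(n - 1, ceiling(rate))
  out <- sig
  for (axis in c("x", "y", "z")) {
    v <- sig[[axis]]
    # reflective padding about the end samples
    padded <- c(2 * v[1] - v[(pad + 1):2], v, 2 * v[n] - v[(n - 1):(n - pad)])
    f <- signal::filtfilt(bf, padded)
    out[[axis]] <- f[(pad + 1):(pad + n)]
  }
  out
}

#' Band-limited resampling of an acceleration signal
#'
#' Rate conversion without phase distortion (needed e.g. to feed 100 Hz
#' wearable recordings to models trained on 60 Hz marker-derived data): when
#' downsampling, a zero-phase Butterworth anti-alias filter is applied at
#' 90% of the new Nyquist frequency, then the series is interpolated at the
#' new sample times. Duration is preserved to within one sample period and
#' event timing is unshifted (zero group delay).
#'
#' @param sig an [accel_signal()].
#' @param target_rate new sampling rate in Hz.
#' @return the resampled signal at `target_rate`.
#' @export
resample_signal <- function(sig, target_rate) {
  check_number(target_rate, "target_rate", min = 0, strict_min = TRUE)
  rate <- signal_rate(sig)
  if (isTRUE(all.equal(rate, target_rate))) return(sig)
  n <- nrow(sig)
  duration <- n / rate
  t_new <- sig$time[1] + seq(0, duration - 1 / target_rate,
                             by = 1 / target_rate)
  low <- if (target_rate < rate) {
    function(v) {
      bf <- signal::butter(8, 0.9 * target_rate / rate, type = "low")
      pad <- min(n - 1, ceiling(rate))
      padded <- c(2 * v[1] - v[(pad + 1):2], v,
                  2 * v[n] - v[(n - 1):(n - pad)])
      signal::filtfilt(bf, padded)[(pad + 1):(pad + n)]
    }
  } else {
    identity
  }
  out <- purrr::map(c(x = "x", y = "y", z = "z"), function(axis) {
    stats::spline(sig$time, low(sig[[axis]]), xout = t_new)$y
  })
  accel_signal(tibble::as_tibble(out), rate = target_rate,
               source = signal_source(sig), subject_id = signal_subject(sig),
               t0 = sig$time[1])
}
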