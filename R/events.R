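#' Gaussian-wavelet transform of vertical acceleration
#'
#' Computes the continuous wavelet transform of the vertical acceleration
#' with a first-derivative-of-Gaussian wavelet (`gaus1`) at a single scale,
#' and its numerical time derivative. Initial contacts appear as local
#' minima of the smoothed signal `s1`; final contacts as local maxima of its
#' derivative `s2`.
#'
#' The scale is defined at a 60 Hz reference rate and rescaled
#' proportionally with the actual sampling rate (`effective scale = scale *
#' rate / 60`) so the physical smoothing width (~ scale / 60 seconds) is the
#' same for 60 Hz marker-derived and 100 Hz wearable signals.
#'
#' Wavelet sign convention: `psi(u) = u * exp(-u^2 / 2)`, so an upward
#' acceleration transient (heel strike) produces a sharp `s1` minimum at the
#' transient. The wavelet has zero mean, which makes the transform
#' insensitive to a constant gravity offset on the vertical axis.
#'
#' @param sig an [accel_signal()], or a numeric vector (then `rate` must be
#'   given).
#' @param axis which axis to transform when `sig` is a signal (default `"z"`,
#'   vertical).
#' @param scale CWT scale at the 60 Hz reference rate (default 10).
#' @param rate sampling rate in Hz; taken from `sig` when it is a signal.
#' @return a `wavelet_signals` tibble with columns `time`, `s1`, `s2`, and
#'   attributes `scale` (requested) and `rate`.
#' @export
wavelet_transform <- function(sig, axis = "z", scale = 10, rate = NULL) {
  if (inherits(sig, "accel_signal")) {
    rate <- signal_rate(sig)
    x <- sig[[axis]]
    t0 <- sig$time[1]
  } else {
    if (is.null(rate)) {
      abort("`rate` is required for a bare numeric series.",
            class = "gaitdx_parameter_error")
    }
    x <- as.numeric(sig)
    t0 <- 0
  }
  check_number(scale, "scale", min = 0, strict_min = TRUE)
  eff <- scale * rate / 60
  n <- length(x)
  if (n <= 2 * eff) {
    abort(sprintf("series of %d samples is too short for scale %g.", n, eff),
          class = "gaitdx_insufficient_data_error")
  }

  half <- ceiling(4 * eff)
  u <- (-half:half) / eff
  kern <- u * exp(-u^2 / 2) / sqrt(eff)

  pad_n <- min(n - 1, half)
  padded <- c(2 * x[1] - x[(pad_n + 1):2], x, 2 * x[n] - x[(n - 1):(n - pad_n)])
  # cross-correlation with the scaled wavelet: s1[i] = sum_j x[i+j] k[j]
  filt <- stats::filter(padded, rev(kern), method = "convolution", sides = 2)
  s1 <- as.numeric(filt[(pad_n + 1):(pad_n + n)])
  # near the edges the kernel overhangs the padded region; extend by reflection
  if (anyNA(s1)) {
    idx <- which(!is.na(s1))
    s1 <- approx(idx, s1[idx], xout = seq_len(n), rule = 2)$y
  }

  s2 <- c(s1[2] - s1[1],
          (s1[3:n] - s1[1:(n - 2)]) / 2,
          s1[n] - s1[n - 1]) * rate

  out <- tibble::tibble(time = t0 + (seq_len(n) - 1) / rate, s1 = s1, s2 = s2)
  structure(out, class = c("wavelet_signals", class(out)),
            scale = scale, rate = rate)
}

#' Detect initial and final contacts
#'
#' Initial contacts (heel strikes) are local minima of the wavelet-smoothed
#' vertical acceleration `s1`; final contacts (toe-offs) are local maxima of
#' its derivative `s2`. Candidate extrema are filtered by topographic
#' prominence (at least `prominence * SD` of the respective series, making
#' detection invariant to amplitude scaling) and by a minimum separation.
#' Each retained IC is then matched to the earliest FC after it; ICs whose
#' matched stance duration is implausible, or that have no FC before the
#' next-but-one IC, are dropped.
#'
#' @param ws a `wavelet_signals` object from [wavelet_transform()].
#' @param min_period_s minimum separation between events of the same type,
#'   in seconds (default 0.4, about half a fast stride).
#' @param prominence prominence threshold as a fraction of the series SD
#'   (default 0.2).
#' @param stance_bounds plausible (min, max) IC-to-FC durations in seconds;
#'   matches outside are discarded (default `c(0.1, 2)`).
#' @return a `gait_events` tibble with columns `event` (`"IC"`/`"FC"`),
#'   `time` (seconds) and `side` (`NA` until [assign_sides()]). An empty
#'   tibble when no events survive (not an error).
#' @export
detect_gait_events <- function(ws, min_period_s = 0.4, prominence = 0.2,
                               stance_bounds = c(0.1, 2)) {
  check_number(min_period_s, "min_period_s", min = 0, strict_min = TRUE)
  rate <- attr(ws, "rate")
  min_sep <- min_period_s * rate

  ic_idx <- prominent_extrema(-ws$s1, prominence * stats::sd(ws$s1), min_sep)
  fc_idx <- prominent_extrema(ws$s2, prominence * stats::sd(ws$s2), min_sep)
  ic_times <- ws$time[ic_idx]
  fc_times <- ws$time[fc_idx]

  keep_ic <- logical(length(ic_times))
  matched_fc <- numeric(length(ic_times))
  for (i in seq_along(ic_times)) {
    limit <- if (i + 2 <= length(ic_times)) ic_times[i + 2] else Inf
    cand <- fc_times[fc_times > ic_times[i] & fc_times < limit]
    cand <- cand[cand - ic_times[i] > stance_bounds[1] &
                 cand - ic_times[i] < stance_bounds[2]]
    if (length(cand) > 0) {
      keep_ic[i] <- TRUE
      matched_fc[i] <- cand[1]
    }
  }

  ic_keep <- ic_times[keep_ic]
  fc_keep <- sort(unique(matched_fc[keep_ic]))
  out <- dplyr::arrange(dplyr::bind_rows(
    tibble::tibble(event = "IC", time = ic_keep, side = NA_character_),
    tibble::tibble(event = "FC", time = fc_keep, side = NA_character_)
  ), .data$time)
  structure(out, class = c("gait_events", class(out)), rate = rate)
}

#' Assign alternating left/right sides to initial contacts
#'
#' With consecutive steps from a single sensor the side of each step is not
#' observable; the first step is assumed left (or right) and sides then
#' alternate strictly.
#'
#' @param events a `gait_events` tibble.
#' @param first_side side of the first IC, `"L"` or `"R"`.
#' @return the events with `side` filled for ICs.
#' @export
assign_sides <- function(events, first_side = c("L", "R")) {
  first_side <- match.arg(first_side)
  ic <- which(events$event == "IC")
  if (length(ic) > 0) {
    sides <- rep(c("L", "R"), length.out = length(ic))
    if (first_side == "R") sides <- rep(c("R", "L"), length.out = length(ic))
    events$side[ic] <- sides
  }
  events
}

# Local maxima of `v` filtered by topographic prominence and greedy minimum
# separation (most prominent first). Returns sorted indices.
prominent_extrema <- function(v, min_prom, min_sep) {
  n <- length(v)
  if (n < 3) return(integer(0))
  is_peak <- which(v[2:(n - 1)] > v[1:(n - 2)] & v[2:(n - 1)] >= v[3:n]) + 1
  if (length(is_peak) == 0) return(integer(0))

  prom <- purrr::map_dbl(is_peak, function(i) {
    h <- v[i]
    left <- if (i > 1) v[1:(i - 1)] else numeric(0)
    higher_l <- which(left > h)
    lmin <- min(left[seq(max(higher_l, 0) + 1, i - 1)])
    right <- if (i < n) v[(i + 1):n] else numeric(0)
    higher_r <- which(right > h)
    rmax_idx <- if (length(higher_r)) min(higher_r) - 1 else length(right)
    rmin <- min(right[seq_len(rmax_idx)])
    h - max(lmin, rmin)
  })
  keep <- is_peak[prom >= min_prom & is.finite(prom)]
  prom <- prom[prom >= min_prom & is.finite(prom)]
  if (length(keep) == 0) return(integer(0))

  ord <- order(prom, decreasing = TRUE)
  accepted <- integer(0)
  for (i in ord) {
    if (all(abs(keep[i] - accepted) >= min_sep)) {
      accepted <- c(accepted, keep[i])
    }
  }
  sort(accepted)
}
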