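#' Configuration for the synthetic walking simulator
#'
#' Describes one subject's gait process and sensor setup. Step intervals are
#' drawn as side-alternating truncated Gaussians (floor 0.2 s); the vertical
#' acceleration is a sum of step-locked harmonics, a sharp
#' derivative-of-Gaussian transient at each initial contact and a
#' second-derivative-of-Gaussian transient at each final contact. Both
#' transient shapes have zero integral, which keeps integration drift in
#' marker mode bounded and makes the wavelet detector's `s1` minimum
#' (resp. `s2` maximum) land on the true IC (resp. FC).
#'
#' The configured `asymmetry_step` is split +/- half between the two sides
#' so the stride mean stays at `stride_mean`.
#'
#' @param stride_mean mean stride time in seconds.
#' @param stride_sd within-subject stride-time SD in seconds.
#' @param stance_fraction mean stance duration as a fraction of stride.
#'   The default 0.15 places the final contact near the quarter-step point,
#'   the natural location of the smoothed derivative maximum for a
#'   step-periodic signal, and keeps it below the step fraction so the
#'   earliest final contact after an initial contact is the one belonging
#'   to it. The single-sensor wavelet method localizes a within-step
#'   toe-off-like event rather than the ipsilateral stance end.
#' @param stance_sd SD of the per-cycle stance fraction.
#' @param asymmetry_step left-right step-time difference in seconds.
#' @param vert_amp amplitude of the fundamental vertical harmonic (m/s^2).
#' @param harmonic_rel relative amplitudes of the step-locked harmonics.
#' @param ap_ratio,ml_ratio anterior-posterior / mediolateral amplitudes as
#'   fractions of the vertical amplitude.
#' @param ic_amp,fc_amp peak amplitudes (m/s^2) of the IC and FC transients.
#' @param ic_width,fc_width Gaussian widths (s) of the IC and FC transients.
#' @param noise_sd wearable sensor noise SD as a fraction of each axis'
#'   signal SD.
#' @param marker_noise_sd marker position noise SD in meters (smooth,
#'   low-pass filtered; default 0).
#' @param gravity logical; add +9.80665 m/s^2 to the wearable vertical axis.
#' @param duration recording duration in seconds.
#' @param rate wearable sampling rate in Hz.
#' @param marker_rate camera sampling rate in Hz.
#' @param first_side side of the first step.
#' @return a `gait_sim_config` list.
#' @export
gait_sim_config <- function(stride_mean = 1.05, stride_sd = 0.022,
                            stance_fraction = 0.15, stance_sd = 0.012,
                            asymmetry_step = 0.005,
                            vert_amp = 0.4, harmonic_rel = c(1, 0.45, 0.2),
                            ap_ratio = 0.6, ml_ratio = 0.45,
                            ic_amp = 3.0, fc_amp = 2.5,
                            ic_width = 0.04, fc_width = 0.05,
                            noise_sd = 0.05, marker_noise_sd = 0,
                            gravity = FALSE, duration = 60,
                            rate = 100, marker_rate = 60,
                            first_side = "L") {
  check_number(stride_mean, "stride_mean", min = 0, strict_min = TRUE)
  check_number(stride_sd, "stride_sd", min = 0)
  check_number(stance_fraction, "stance_fraction", min = 0, max = 1,
               strict_min = TRUE)
  if (stance_fraction >= 1) {
    abort("stance_fraction must be in (0, 1).",
          class = "gaitdx_parameter_error")
  }
  check_number(duration, "duration", min = 3 * stride_mean)
  check_number(rate, "rate", min = 0, strict_min = TRUE)
  structure(list(
    stride_mean = stride_mean, stride_sd = stride_sd,
    stance_fraction = stance_fraction, stance_sd = stance_sd,
    asymmetry_step = asymmetry_step,
    vert_amp = vert_amp, harmonic_rel = harmonic_rel,
    ap_ratio = ap_ratio, ml_ratio = ml_ratio,
    ic_amp = ic_amp, fc_amp = fc_amp,
    ic_width = ic_width, fc_width = fc_width,
    noise_sd = noise_sd, marker_noise_sd = marker_noise_sd,
    gravity = gravity, duration = duration,
    rate = rate, marker_rate = marker_rate, first_side = first_side
  ), class = "gait_sim_config")
}

#' Simulate one subject in both modalities
#'
#' Generates ground-truth gait events, builds the continuous-time
#' acceleration described in [gait_sim_config()], and renders it as (a) a
#' wearable accelerometer recording (sensor noise, optional gravity offset,
#' `rate` Hz) and (b) a marker trajectory (positions obtained by double
#' cumulative integration of the 60 Hz sampled acceleration — the exact
#' discrete inverse of the second difference — with sub-0.1 Hz drift
#' removed), so that double differencing the marker mode recovers the true
#' acceleration.
#'
#' @param cfg a [gait_sim_config()].
#' @param subject_id identifier attached to the outputs.
#' @param seed RNG seed for reproducibility (optional).
#' @return a list with elements `wearable` ([accel_signal()]), `marker`
#'   ([marker_trajectory()]) and `truth` (list: `events`, `cycles`,
#'   `features`, `accel` — the ideal 60 Hz acceleration).
#' @export
simulate_subject <- function(cfg, subject_id = "S1", seed = NULL) {
  stopifnot(inherits(cfg, "gait_sim_config"))
  with_seed(seed, {
    ev <- simulate_events(cfg)
    truth <- ground_truth_from_events(ev, cfg)

    t_wear <- seq(0, cfg$duration - 1 / cfg$rate, by = 1 / cfg$rate)
    aw <- accel_waveform(t_wear, ev, cfg)
    for (axis in c("x", "y", "z")) {
      s <- stats::sd(aw[[axis]])
      aw[[axis]] <- aw[[axis]] + rnorm(length(t_wear), sd = cfg$noise_sd * s)
    }
    if (isTRUE(cfg$gravity)) aw$z <- aw$z + GRAVITY_MS2
    wearable <- accel_signal(aw, rate = cfg$rate, source = "wearable",
                             subject_id = subject_id)

    t_mark <- seq(0, cfg$duration - 1 / cfg$marker_rate,
                  by = 1 / cfg$marker_rate)
    am <- accel_waveform(t_mark, ev, cfg)
    pos <- purrr::map(am, ~ integrate_to_position(.x, cfg$marker_rate))
    if (cfg$marker_noise_sd > 0) {
      bf <- signal::butter(2, min(10 / (cfg$marker_rate / 2), 0.9),
                           type = "low")
      pos <- purrr::map(pos, function(p) {
        p + signal::filtfilt(bf, rnorm(length(p), sd = cfg$marker_noise_sd))
      })
    }
    pos$z <- pos$z + 1.0  # nominal sacral marker height
    marker <- marker_trajectory(tibble::as_tibble(pos),
                                rate = cfg$marker_rate,
                                subject_id = subject_id)
    truth$accel <- accel_signal(tibble::as_tibble(am), rate = cfg$marker_rate,
                                source = "marker-derived",
                                subject_id = subject_id)
    list(wearable = wearable, marker = marker, truth = truth)
  })
}

# Draw side-alternating IC times and matched FC times.
simulate_events <- function(cfg) {
  step_mean <- cfg$stride_mean / 2
  step_sd <- cfg$stride_sd / sqrt(2)
  offset <- c(L = cfg$asymmetry_step / 2, R = -cfg$asymmetry_step / 2)
  margin <- 1.0
  sides <- character(0)
  steps <- numeric(0)
  side <- cfg$first_side
  t_total <- 0
  while (t_total < cfg$duration - 2 * margin) {
    s <- max(0.2, rnorm(1, step_mean + offset[[side]], step_sd))
    steps <- c(steps, s)
    sides <- c(sides, side)
    side <- if (side == "L") "R" else "L"
    t_total <- t_total + s
  }
  ic <- margin + cumsum(c(0, head(steps, -1)))
  m <- length(ic)
  # stance for IC_i spans a fraction of the stride starting there; keep it
  # inside the step so the earliest-FC-after-IC matching is unambiguous
  stride_i <- c(steps[-m] + steps[-1], steps[m] + step_mean)
  sf <- rnorm(m, cfg$stance_fraction, cfg$stance_sd)
  sf <- pmin(pmax(sf, 0.05), 0.95 * steps / stride_i)
  fc <- ic + sf * stride_i
  list(ic = ic, fc = fc, sides = sides, steps = steps)
}

# True cycle table and feature vector by direct arithmetic on the drawn
# intervals (independent of the extraction pipeline).
ground_truth_from_events <- function(ev, cfg) {
  m <- length(ev$ic)
  step <- c(diff(ev$ic), NA)
  stride <- c(ev$ic[3:m] - ev$ic[1:(m - 2)], NA, NA)
  stance <- ev$fc - ev$ic
  swing <- stride - stance
  cycles <- tibble::tibble(cycle = seq_len(m) - 1L, side = ev$sides,
                           step_time = step, stance_time = stance,
                           stride_time = stride, swing_time = swing)
  feats <- stats::setNames(rep(NA_real_, 16), gait_feature_names())
  tabs <- list(StepTime = step, StanceTime = stance,
               StrideTime = stride, SwingTime = swing)
  for (p in names(tabs)) {
    v <- tabs[[p]]; s <- ev$sides; ok <- !is.na(v)
    feats[p] <- mean(v[ok])
    feats[paste(p, "MV")] <- pop_sd(v[ok])
    feats[paste(p, "SV")] <- sqrt((pop_var(v[ok & s == "L"]) +
                                   pop_var(v[ok & s == "R"])) / 2)
    feats[paste(p, "SA")] <- abs(mean(v[ok & s == "L"]) -
                                 mean(v[ok & s == "R"]))
  }
  events <- dplyr::arrange(dplyr::bind_rows(
    tibble::tibble(event = "IC", time = ev$ic, side = ev$sides),
    tibble::tibble(event = "FC", time = ev$fc, side = NA_character_)
  ), .data$time)
  class(events) <- c("gait_events", class(events))
  list(events = events, cycles = cycles,
       features = tibble::as_tibble(as.list(feats)))
}

# Continuous-time 3-axis acceleration at times `t` (seconds).
accel_waveform <- function(t, ev, cfg) {
  # step phase: piecewise linear through the IC times, extended at both ends
  mean_step <- mean(ev$steps)
  knots <- c(ev$ic[1] - 3:1 * mean_step, ev$ic,
             ev$ic[length(ev$ic)] + 1:3 * mean_step)
  phase <- approx(knots, seq_along(knots) - 1, xout = t, rule = 2)$y

  harmonics <- function(ph, rel, phases) {
    out <- 0
    for (h in seq_along(rel)) {
      out <- out + rel[h] * sin(2 * pi * h * ph + phases[h])
    }
    out
  }
  # fundamental phase pi: its wavelet-smoothed derivative is minimal at the
  # ICs, consistent with the heel-strike transients
  hz <- cfg$vert_amp * harmonics(phase, cfg$harmonic_rel, c(pi, 1.1, 2.3))
  # Transients are first/second Gaussian derivatives (zero integral, so no
  # velocity drift accumulates in marker mode). The heel-strike transient
  # puts a sharp s1 minimum on the IC; the toe-off transient puts an s2
  # maximum on the FC. With the default stance fraction the FC sits near the
  # quarter-step point, where the fundamental's own s2 maximum reinforces it.
  gp <- function(u) -u * exp(-u^2 / 2) / exp(-0.5)
  mx <- function(u) (u^2 - 1) * exp(-u^2 / 2)
  ic_shape <- function(t0, width) {
    u <- outer(t, t0, function(a, b) (a - b) / width)
    rowSums(gp(u))
  }
  fc_shape <- function(t0, width) {
    u <- outer(t, t0, function(a, b) (a - b) / width)
    rowSums(mx(u))
  }
  z <- hz + cfg$ic_amp * ic_shape(ev$ic, cfg$ic_width) +
    cfg$fc_amp * fc_shape(ev$fc, cfg$fc_width)
  x <- cfg$ap_ratio *
    (cfg$vert_amp * harmonics(phase + 0.25, cfg$harmonic_rel, c(0.4, 1.6, 2.9)))
  y <- cfg$ml_ratio * cfg$vert_amp * sin(pi * phase + 0.7)  # stride-frequency sway

  # gait starts and stops inside the recording: raised-cosine amplitude
  # envelope around the event span, so no steps exist outside it
  last_ev <- max(ev$ic[length(ev$ic)], ev$fc[length(ev$fc)])
  env <- ramp_envelope(t, ev$ic[1] - 0.8 * mean_step,
                       ev$ic[1] - 0.25 * mean_step,
                       last_ev + 0.25 * mean_step, last_ev + 0.8 * mean_step)
  list(x = x * env, y = y * env, z = z * env)
}

ramp_envelope <- function(t, up0, up1, down0, down1) {
  env <- rep(1, length(t))
  env[t <= up0 | t >= down1] <- 0
  i <- t > up0 & t < up1
  env[i] <- 0.5 - 0.5 * cos(pi * (t[i] - up0) / (up1 - up0))
  i <- t > down0 & t < down1
  env[i] <- 0.5 + 0.5 * cos(pi * (t[i] - down0) / (down1 - down0))
  env
}

# Double cumulative integration (exact discrete inverse of the second
# difference) followed by sub-0.1 Hz drift removal so positions stay bounded.
integrate_to_position <- function(a, rate) {
  a0 <- a - mean(a)
  n <- length(a0)
  # phased so the centre-aligned second difference returns a0[k+1] at sample
  # k+1: p starts at rest and accumulates a0 with a two-sample lead
  b <- c(0, 0, a0[2:(n - 1)])
  p <- cumsum(cumsum(b)) / rate^2
  bf <- signal::butter(2, 0.1 / (rate / 2), type = "low")
  n <- length(p)
  pad <- min(n - 1, 10 * rate)
  padded <- c(2 * p[1] - p[(pad + 1):2], p, 2 * p[n] - p[(n - 1):(n - pad)])
  trend <- signal::filtfilt(bf, padded)[(pad + 1):(pad + n)]
  p - trend
}

#' Group-level simulation presets
#'
#' Distributions from which per-subject [gait_sim_config()]s are drawn.
#' The `"healthy"` preset is a steady older-adult walker. The `"pad"`
#' preset encodes the qualitative group differences of claudication gait:
#' slower (longer) strides, more than doubled stride/swing variability and
#' increased step asymmetry. `effect` scales the PAD-healthy differences
#' (0 = identical groups, 1 = default separation, 2 = doubled).
#'
#' @param group `"healthy"` or `"pad"`.
#' @param effect effect-size multiplier for the group differences.
#' @return a list of group-level parameter distributions.
#' @export
sim_preset <- function(group = c("healthy", "pad"), effect = 1) {
  group <- match.arg(group)
  check_number(effect, "effect", min = 0)
  e <- if (group == "pad") effect else 0
  list(
    group = group, effect = effect,
    stride_mean_mu = 1.05 + 0.12 * e, stride_mean_sd = 0.04,
    stride_sd_mu = 0.022 * (1 + 1.3 * e), stride_sd_cv = 0.2,
    asym_mu = 0.005 + 0.015 * e, asym_sd = 0.002 + 0.002 * e,
    stance_fraction = 0.15, stance_sd_mu = 0.012 * (1 + 0.8 * e)
  )
}

draw_config <- function(preset, duration, rate, ...) {
  ln_sd <- sqrt(log(1 + preset$stride_sd_cv^2))
  gait_sim_config(
    stride_mean = max(0.6, rnorm(1, preset$stride_mean_mu,
                                 preset$stride_mean_sd)),
    stride_sd = stats::rlnorm(1, log(preset$stride_sd_mu) - ln_sd^2 / 2,
                              ln_sd),
    stance_fraction = preset$stance_fraction,
    stance_sd = stats::rlnorm(1, log(preset$stance_sd_mu) - ln_sd^2 / 2,
                              ln_sd),
    asymmetry_step = abs(rnorm(1, preset$asym_mu, preset$asym_sd)),
    duration = duration, rate = rate, ...
  )
}

#' Simulate a labeled cohort in both modalities
#'
#' Per-subject gait parameters are drawn from the group-level preset
#' distributions; each subject is then rendered in marker and wearable mode
#' with shared ground-truth events.
#'
#' @param n_healthy,n_pad subjects per group.
#' @param healthy,pad group presets from [sim_preset()].
#' @param duration recording duration per subject in seconds (default 60).
#' @param rate wearable sampling rate in Hz.
#' @param seed RNG seed; the whole cohort is deterministic under it.
#' @param ... further fixed arguments passed to [gait_sim_config()].
#' @return a tibble with columns `subject_id`, `label`, and list-columns
#'   `marker`, `wearable`, `truth`.
#' @export
simulate_cohort <- function(n_healthy, n_pad,
                            healthy = sim_preset("healthy"),
                            pad = sim_preset("pad"),
                            duration = 60, rate = 100, seed = NULL, ...) {
  stopifnot(n_healthy >= 1, n_pad >= 1)
  with_seed(seed, {
    labels <- c(rep("healthy", n_healthy), rep("PAD", n_pad))
    ids <- sprintf("S%02d", seq_along(labels))
    rows <- purrr::map2(ids, labels, function(id, lab) {
      preset <- if (lab == "PAD") pad else healthy
      cfg <- draw_config(preset, duration = duration, rate = rate, ...)
      sim <- simulate_subject(cfg, subject_id = id)
      list(subject_id = id, label = lab, marker = sim$marker,
           wearable = sim$wearable, truth = sim$truth)
    })
    tibble::tibble(
      subject_id = purrr::map_chr(rows, "subject_id"),
      label = purrr::map_chr(rows, "label"),
      marker = purrr::map(rows, "marker"),
      wearable = purrr::map(rows, "wearable"),
      truth = purrr::map(rows, "truth")
    )
  })
}

#' Select one modality of a simulated cohort
#'
#' Reduces a [simulate_cohort()] tibble to the `subject_id` / `label` /
#' `signal` layout used by [load_cohort()], with marker trajectories
#' converted to filtered marker-derived acceleration when requested.
#'
#' @param cohort a simulated cohort tibble.
#' @param modality `"marker"` (double-differenced, Butterworth-filtered) or
#'   `"wearable"`.
#' @param cutoff_hz,order Butterworth parameters for the marker path.
#' @return cohort tibble with a `signal` list-column of acceleration signals.
#' @export
cohort_modality <- function(cohort, modality = c("marker", "wearable"),
                            cutoff_hz = 15, order = 4) {
  modality <- match.arg(modality)
  signal <- if (modality == "wearable") {
    cohort$wearable
  } else {
    purrr::map(cohort$marker, function(traj) {
      butterworth_lowpass(derive_acceleration(traj), order = order,
                          cutoff_hz = cutoff_hz)
    })
  }
  tibble::tibble(subject_id = cohort$subject_id, label = cohort$label,
                 modality = modality, signal = signal)
}
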