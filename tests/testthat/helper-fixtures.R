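# Shared fixtures built in code at test time.

# A bare 3-axis signal from a vertical-axis vector.
axis_signal <- function(z, rate = 60, source = "wearable") {
  accel_signal(tibble::tibble(x = 0 * z, y = 0 * z, z = z),
               rate = rate, source = source)
}

# Pull IC / FC times out of a gait_events tibble.
ic_times <- function(ev) ev$time[ev$event == "IC"]
fc_times <- function(ev) ev$time[ev$event == "FC"]

# Fraction of true events matched by a detection within tol seconds, and the
# per-true-event absolute errors.
match_events <- function(true_t, det_t, tol = 0.04) {
  if (length(det_t) == 0) {
    return(list(recall = 0, abs_err = rep(Inf, length(true_t))))
  }
  err <- vapply(true_t, function(t) min(abs(det_t - t)), numeric(1))
  list(recall = mean(err <= tol), abs_err = err)
}

# Detected events for one simulated subject via the standard marker path.
detect_marker_events <- function(sim) {
  acc <- butterworth_lowpass(derive_acceleration(sim$marker))
  assign_sides(detect_gait_events(wavelet_transform(acc)), "L")
}

# Small all-wearable cohort with per-subject stride means.
wearable_cohort_strides <- function(strides, labels, seed, duration = 30,
                                    noise_sd = 0.05) {
  rows <- purrr::map(seq_along(strides), function(i) {
    cfg <- gait_sim_config(duration = duration, stride_mean = strides[i],
                           noise_sd = noise_sd)
    sim <- simulate_subject(cfg, subject_id = sprintf("S%02d", i),
                            seed = seed + i)
    tibble::tibble(subject_id = sprintf("S%02d", i), label = labels[i],
                   signal = list(sim$wearable))
  })
  dplyr::bind_rows(rows)
}
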