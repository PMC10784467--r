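make_traj <- function(z, rate = 60) {
  marker_trajectory(tibble::tibble(x = 0 * z, y = 0 * z, z = z), rate = rate)
}

test_that("double differencing is exact on constants and quadratics", {
  t <- (0:299) / 60
  expect_equal(derive_acceleration(make_traj(rep(1.3, 300)))$z, rep(0, 298))

  # free-fall quadratic: the second difference is exact, not approximate
  acc <- derive_acceleration(make_traj(0.5 * 9.81 * t^2))
  expect_equal(acc$z, rep(9.81, 298), tolerance = 1e-9)
  expect_equal(nrow(acc), 298)
  expect_equal(signal_source(acc), "marker-derived")
  # timestamps aligned to the centre sample
  expect_equal(acc$time[1], t[2])
})

test_that("double differencing a sinusoid matches the analytic second derivative", {
  t <- (0:599) / 60
  traj <- make_traj(0.02 * sin(2 * pi * t))
  acc <- derive_acceleration(traj)
  analytic_amp <- 0.02 * (2 * pi)^2
  measured_amp <- sqrt(2) * sqrt(mean(acc$z^2))
  expect_lt(abs(measured_amp / analytic_amp - 1), 0.002)
  # phase: finite differences attenuate but do not shift a sinusoid
  expect_equal(acc$z, -0.02 * (2 * pi)^2 *
                 (sin(pi / 60) / (pi / 60))^2 * sin(2 * pi * acc$time),
               tolerance = 1e-9)
})

test_that("differencing is linear and refuses short inputs", {
  z1 <- rnorm(50); z2 <- rnorm(50)
  a1 <- derive_acceleration(make_traj(z1))$z
  a2 <- derive_acceleration(make_traj(z2))$z
  a12 <- derive_acceleration(make_traj(2 * z1 - 3 * z2))$z
  expect_equal(a12, 2 * a1 - 3 * a2)
  expect_error(marker_trajectory(tibble::tibble(x = 1:2, y = 1:2, z = 1:2),
                                 rate = 60),
               class = "gaitdx_insufficient_data_error")
})

test_that("zero-phase Butterworth matches its squared designed response", {
  rate <- 60
  t <- (0:(rate * 10 - 1)) / rate
  interior <- t > 1 & t < max(t) - 1
  bf <- signal::butter(4, 15 / (rate / 2), type = "low")
  gain_at <- function(f_hz) {
    # transfer function of the designed digital filter at f_hz, squared
    # because the forward-backward pass applies it twice
    w <- 2 * pi * f_hz / rate
    e <- exp(-1i * w * (seq_along(bf$b) - 1))
    Mod(sum(bf$b * e) / sum(bf$a * e))^2
  }
  for (f in c(15, 25)) {
    sig <- axis_signal(sin(2 * pi * f * t), rate = rate)
    out <- butterworth_lowpass(sig, order = 4, cutoff_hz = 15)
    amp <- sqrt(2) * sqrt(mean(out$z[interior]^2))
    expect_lt(abs(amp - gain_at(f)), 0.05 * max(gain_at(f), 0.05))
  }
  # headline contract: ~0.5 at the cutoff, <=0.05 in the stopband
  sig15 <- butterworth_lowpass(axis_signal(sin(2 * pi * 15 * t), rate))
  expect_equal(sqrt(2) * sqrt(mean(sig15$z[interior]^2)), 0.5,
               tolerance = 0.05)
  sig25 <- butterworth_lowpass(axis_signal(sin(2 * pi * 25 * t), rate))
  expect_lte(sqrt(2) * sqrt(mean(sig25$z[interior]^2)), 0.05)

  # DC gain 1 and length preservation
  const <- butterworth_lowpass(axis_signal(rep(2.5, 600), rate))
  expect_equal(const$z, rep(2.5, 600), tolerance = 1e-6)

  expect_error(butterworth_lowpass(axis_signal(rnorm(100), rate),
                                   cutoff_hz = 30),
               class = "gaitdx_parameter_error")
})

test_that("filtering is idempotent on band-limited signals", {
  rate <- 60
  t <- (0:599) / rate
  sig <- axis_signal(sin(2 * pi * 2 * t), rate)  # well below 15 Hz cutoff
  once <- butterworth_lowpass(sig)
  twice <- butterworth_lowpass(once)
  interior <- t > 1 & t < max(t) - 1
  rms <- function(x) sqrt(mean(x^2))
  expect_lt(abs(rms(twice$z[interior]) / rms(once$z[interior]) - 1), 0.01)
})

test_that("resampling preserves identity, amplitude and duration", {
  rate <- 100
  t <- (0:999) / rate
  sig <- axis_signal(sin(2 * pi * t), rate)

  same <- resample_signal(sig, 100)
  expect_equal(same$z, sig$z)

  down <- resample_signal(sig, 60)
  expect_equal(signal_rate(down), 60)
  expect_equal(nrow(down), 600, tolerance = 1)
  interior <- down$time > 1 & down$time < 9
  amp <- sqrt(2) * sqrt(mean(down$z[interior]^2))
  expect_lt(abs(amp - 1), 0.01)
  # sample values match the analytic sinusoid at the new sample times
  expect_equal(down$z[interior], sin(2 * pi * down$time[interior]),
               tolerance = 0.02)
})

test_that("marker gap filling interpolates short gaps and splits long ones", {
  z <- c(1, 1.0, NA, 2.0, 3, 4, 5, 6, 7, 8)
  traj <- make_traj(z)
  filled <- fill_marker_gaps(traj, max_gap = 6)
  expect_equal(filled$z[3], 1.5)
  expect_equal(unique(filled$segment), 1L)

  no_gap <- fill_marker_gaps(make_traj(1:10 / 10))
  expect_equal(no_gap$z, 1:10 / 10)

  z2 <- c(1:5 / 10, rep(NA, 3), 9:14 / 10)
  split2 <- fill_marker_gaps(make_traj(z2), max_gap = 2)
  expect_equal(dplyr::n_distinct(split2$segment), 2)
  expect_false(anyNA(split2$z))

  expect_error(fill_marker_gaps(make_traj(rep(NA_real_, 10))),
               class = "gaitdx_unusable_signal_error")
})
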