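test_that("simulation is deterministic under a seed", {
  cfg <- gait_sim_config(duration = 12)
  a <- simulate_subject(cfg, seed = 99)
  b <- simulate_subject(cfg, seed = 99)
  expect_identical(a$wearable$z, b$wearable$z)
  expect_identical(a$marker$z, b$marker$z)
  expect_identical(a$truth$events$time, b$truth$events$time)

  co1 <- simulate_cohort(2, 2, duration = 10, seed = 7)
  co2 <- simulate_cohort(2, 2, duration = 10, seed = 7)
  expect_identical(co1$wearable[[3]]$z, co2$wearable[[3]]$z)
})

test_that("degenerate configs produce perfectly regular gait", {
  cfg <- gait_sim_config(duration = 20, stride_sd = 0, stance_sd = 0,
                         asymmetry_step = 0, noise_sd = 0)
  sim <- simulate_subject(cfg, seed = 1)
  tf <- sim$truth$features
  expect_equal(tf$`StrideTime MV`, 0, tolerance = 1e-12)
  expect_equal(tf$`StepTime SV`, 0, tolerance = 1e-12)
  expect_equal(tf$`StepTime SA`, 0, tolerance = 1e-12)
  steps <- diff(ic_times(sim$truth$events))
  expect_equal(diff(range(steps)), 0, tolerance = 1e-12)
})

test_that("marker mode round-trips through double differencing", {
  cfg <- gait_sim_config(duration = 30)
  sim <- simulate_subject(cfg, seed = 42)
  acc <- butterworth_lowpass(derive_acceleration(sim$marker))
  truth <- sim$truth$accel
  idx <- match(round(acc$time * 60), round(truth$time * 60))
  ok <- !is.na(idx) & acc$time > 0.5 & acc$time < max(acc$time) - 0.5
  for (axis in c("x", "y", "z")) {
    nrmse <- sqrt(mean((acc[[axis]][ok] - truth[[axis]][idx[ok]])^2)) /
      stats::sd(truth[[axis]][idx[ok]])
    expect_lt(nrmse, 0.05)
  }
})

test_that("ground truth is self-consistent with the feature definitions", {
  cfg <- gait_sim_config(duration = 40)
  sim <- simulate_subject(cfg, seed = 13)
  truth <- sim$truth
  # the pipeline's cycle extraction and feature formulas, applied to the
  # true events, must reproduce the independently computed ground truth
  f <- compute_gait_features(extract_cycles(truth$events))
  for (nm in gait_feature_names()) {
    expect_equal(f[[nm]], truth$features[[nm]], tolerance = 1e-10)
  }
  # paired modalities share the event process
  expect_identical(truth$events, sim$truth$events)
})

test_that("cohort generation respects counts, labels and presets", {
  co <- simulate_cohort(3, 4, duration = 10, seed = 5)
  expect_equal(nrow(co), 7)
  expect_equal(sum(co$label == "healthy"), 3)
  expect_equal(sum(co$label == "PAD"), 4)
  expect_s3_class(co$marker[[1]], "marker_trajectory")
  expect_s3_class(co$wearable[[1]], "accel_signal")

  mc <- cohort_modality(co, "marker")
  expect_s3_class(mc$signal[[1]], "accel_signal")
  expect_equal(signal_source(mc$signal[[1]]), "marker-derived")

  wc <- cohort_modality(co, "wearable")
  expect_equal(signal_rate(wc$signal[[1]]), 100)
})

test_that("the PAD preset increases stride time, variability and asymmetry", {
  h <- sim_preset("healthy")
  p <- sim_preset("pad", effect = 1)
  expect_gt(p$stride_mean_mu, h$stride_mean_mu)
  expect_gte(p$stride_sd_mu / h$stride_sd_mu, 2)
  expect_gt(p$asym_mu, h$asym_mu)
  p0 <- sim_preset("pad", effect = 0)
  expect_equal(p0$stride_sd_mu, h$stride_sd_mu)
})

test_that("identical group configs are indistinguishable to a classifier", {
  accs <- purrr::map_dbl(1:3, function(s) {
    co <- simulate_cohort(10, 10, pad = sim_preset("pad", effect = 0),
                          duration = 40, seed = 400 + s)
    rep <- run_path(4, marker_cohort = cohort_modality(co, "marker"),
                    seed = 500 + s)
    rep$metrics[["accuracy"]]
  })
  expect_gte(mean(accs), 0.3)
  expect_lte(mean(accs), 0.7)
})

test_that("gravity offset does not disturb event detection", {
  cfg_g <- gait_sim_config(duration = 20, gravity = TRUE)
  cfg_0 <- gait_sim_config(duration = 20, gravity = FALSE)
  sim_g <- simulate_subject(cfg_g, seed = 33)
  sim_0 <- simulate_subject(cfg_0, seed = 33)
  expect_equal(mean(sim_g$wearable$z) - mean(sim_0$wearable$z), 9.80665,
               tolerance = 0.05)
  ic_g <- ic_times(detect_gait_events(wavelet_transform(sim_g$wearable)))
  ic_0 <- ic_times(detect_gait_events(wavelet_transform(sim_0$wearable)))
  expect_equal(ic_g, ic_0)
})
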