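events_fixture <- function(ic, sides, fc) {
  structure(
    dplyr::arrange(dplyr::bind_rows(
      tibble::tibble(event = "IC", time = ic, side = sides),
      tibble::tibble(event = "FC", time = fc, side = NA_character_)),
      time),
    class = c("gait_events", class(tibble::tibble())))
}

test_that("cycle extraction reproduces the event-time definitions", {
  ev <- events_fixture(c(0, 0.55, 1.10, 1.65), c("L", "R", "L", "R"),
                       c(0.70, 1.25))
  cyc <- extract_cycles(ev)
  expect_equal(nrow(cyc), 4)
  expect_equal(cyc$step_time[1], 0.55)
  expect_equal(cyc$stride_time[1], 1.10)
  expect_equal(cyc$stance_time[1], 0.70)
  expect_equal(cyc$swing_time[1], 0.40)
  expect_equal(cyc$side, c("L", "R", "L", "R"))
  # trailing cycles miss what their successors cannot provide
  expect_true(is.na(cyc$stride_time[3]))
  expect_true(is.na(cyc$step_time[4]))
  # swing = stride - stance wherever both are defined
  ok <- !is.na(cyc$swing_time)
  expect_equal(cyc$swing_time[ok], cyc$stride_time[ok] - cyc$stance_time[ok])
})

test_that("fewer than three ICs yield an empty cycle table", {
  ev <- events_fixture(c(0, 0.55), c("L", "R"), 0.2)
  expect_equal(nrow(extract_cycles(ev)), 0)
})

test_that("perfectly periodic gait has zero variability", {
  ic <- seq(0, by = 0.55, length.out = 20)
  fc <- ic + 0.15
  ev <- events_fixture(ic, rep(c("L", "R"), 10), fc)
  f <- compute_gait_features(extract_cycles(ev))
  expect_equal(f$StrideTime, 1.10)
  expect_equal(f$`StepTime MV`, 0)
  expect_equal(f$`StrideTime SV`, 0)
  expect_equal(f$`SwingTime SA`, 0)
})

test_that("the variability formulas match hand evaluation", {
  # left step times {0.5, 0.5}, right {0.7, 0.7}
  cyc <- tibble::tibble(
    cycle = 0:3, side = c("L", "R", "L", "R"),
    step_time = c(0.5, 0.7, 0.5, 0.7),
    stance_time = 0.2, stride_time = 1.2, swing_time = 1.0)
  f <- compute_gait_features(cyc)
  expect_equal(f$StepTime, 0.6)
  expect_equal(f$`StepTime MV`, 0.1)      # population SD of {.5,.7,.5,.7}
  expect_equal(f$`StepTime SV`, 0)        # zero within-side variance
  expect_equal(f$`StepTime SA`, 0.2)

  # SV = sqrt((Var_L + Var_R) / 2) with population variances
  cyc2 <- tibble::tibble(
    cycle = 0:3, side = c("L", "L", "R", "R"),
    step_time = c(0.5, 0.9, 0.2, 1.0),    # Var_L = 0.04, Var_R = 0.16
    stance_time = 0.2, stride_time = 1.2, swing_time = 1.0)
  f2 <- compute_gait_features(cyc2)
  expect_equal(f2$`StepTime SV`, sqrt(0.10), tolerance = 1e-12)
})

test_that("side-symmetric tables give zero asymmetry and relabeling invariance", {
  set.seed(4)
  n <- 20
  vals <- rnorm(n, 1.1, 0.05)
  cyc <- tibble::tibble(cycle = seq_len(2 * n) - 1,
                        side = rep(c("L", "R"), n),
                        step_time = rep(vals, each = 2) / 2,
                        stance_time = rep(vals, each = 2) * 0.3,
                        stride_time = rep(vals, each = 2),
                        swing_time = rep(vals, each = 2) * 0.7)
  f <- compute_gait_features(cyc)
  expect_equal(f$`StrideTime SA`, 0)

  flipped <- dplyr::mutate(cyc, side = ifelse(side == "L", "R", "L"))
  ff <- compute_gait_features(flipped)
  for (p in c("StepTime", "StrideTime")) {
    expect_equal(f[[paste(p, "MV")]], ff[[paste(p, "MV")]])
    expect_equal(f[[paste(p, "SV")]], ff[[paste(p, "SV")]])
    expect_equal(f[[paste(p, "SA")]], ff[[paste(p, "SA")]])
  }
})

test_that("features are positively homogeneous in time", {
  ic <- cumsum(c(0, rep(c(0.5, 0.62), 10)))
  ev <- events_fixture(ic, rep(c("L", "R"), length.out = length(ic)),
                       ic + 0.18)
  f1 <- compute_gait_features(extract_cycles(ev))
  ev3 <- events_fixture(ic * 3, rep(c("L", "R"), length.out = length(ic)),
                        (ic + 0.18) * 3)
  f3 <- compute_gait_features(extract_cycles(ev3))
  for (nm in gait_feature_names()) {
    expect_equal(f3[[nm]], 3 * f1[[nm]], tolerance = 1e-10)
  }
})

test_that("wearable bouts with few cycles emit only the four base means", {
  ic <- seq(0, by = 0.55, length.out = 8)  # 3 complete cycles per side
  ev <- events_fixture(ic, rep(c("L", "R"), 4), ic + 0.15)
  f <- compute_gait_features(extract_cycles(ev), modality = "wearable",
                             min_cycles_variability = 10)
  expect_false(is.na(f$StrideTime))
  expect_true(is.na(f$`StrideTime SV`))
  expect_true(attr(f, "core4_only"))
  # marker modality computes everything from the same table
  fm <- compute_gait_features(extract_cycles(ev), modality = "marker")
  expect_false(is.na(fm$`StrideTime SV`))
})

test_that("per-subject mean imputation follows the stated rule", {
  tbl <- tibble::tibble(
    subject_id = c("a", "a", "a", "b", "b"),
    label = "PAD",
    StepTime = c(0.5, NA, 0.7, 1.0, 1.2),
    StrideTime = c(NA, NA, NA, 2.0, NA))
  out <- suppressWarnings(impute_gait_features(tbl))
  expect_equal(out$StepTime[2], 0.6)
  expect_equal(out$StrideTime[5], 2.0)
  expect_true(all(is.na(out$StrideTime[1:3])))  # nothing to impute from
  expect_warning(impute_gait_features(tbl), "StrideTime")

  clean <- tibble::tibble(subject_id = "a", StepTime = c(1, 2))
  expect_equal(impute_gait_features(clean), clean)
})

test_that("feature subsets project in order and reject unknown names", {
  f <- tibble::as_tibble(as.list(stats::setNames(seq_len(16),
                                                 gait_feature_names())))
  expect_equal(names(select_gait_features(f, "all")), gait_feature_names())
  rf4 <- select_gait_features(f, "rf4")
  expect_equal(names(rf4),
               c("SwingTime MV", "SwingTime SV", "StrideTime SV",
                 "StepTime SA"))
  expect_equal(length(feature_subset("logit8")), 8)
  expect_equal(feature_subset("core4"),
               c("StepTime", "StanceTime", "StrideTime", "SwingTime"))
  expect_error(select_gait_features(f, c("StepTime", "FooTime")),
               class = "gaitdx_parameter_error")
})
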