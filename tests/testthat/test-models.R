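fake_cohort <- function(n_h = 25, n_p = 27) {
  tibble::tibble(
    subject_id = sprintf("S%02d", seq_len(n_h + n_p)),
    label = c(rep("healthy", n_h), rep("PAD", n_p)))
}

test_that("subject splits match exact per-label counts", {
  cohort <- fake_cohort(25, 27)
  sp <- split_cohort(cohort,
                     list(test = c(healthy = 6, PAD = 7),
                          validation = c(healthy = 4, PAD = 4)),
                     seed = 1)
  lab <- function(ids) table(cohort$label[cohort$subject_id %in% ids])
  expect_equal(as.numeric(lab(sp$train)[c("healthy", "PAD")]), c(15, 16))
  expect_equal(as.numeric(lab(sp$test)[c("healthy", "PAD")]), c(6, 7))
  expect_equal(as.numeric(lab(sp$validation)[c("healthy", "PAD")]), c(4, 4))
  # partition: no subject in two sets
  all_ids <- c(sp$train, sp$test, sp$validation)
  expect_equal(sort(all_ids), sort(cohort$subject_id))
  expect_equal(anyDuplicated(all_ids), 0)

  sp2 <- split_cohort(cohort,
                      list(test = c(healthy = 6, PAD = 7),
                           validation = c(healthy = 4, PAD = 4)),
                      seed = 1)
  expect_identical(sp, sp2)
  sp3 <- split_cohort(cohort,
                      list(test = c(healthy = 6, PAD = 7)), seed = 2)
  expect_false(identical(sp3$test, sp$test))

  expect_error(split_cohort(cohort, list(test = c(healthy = 30, PAD = 1))),
               class = "gaitdx_parameter_error")
})

test_that("windowing follows floor arithmetic and guards degenerate SD", {
  z <- rnorm(350)
  sig <- accel_signal(tibble::tibble(x = z, y = z, z = z), rate = 100,
                      subject_id = "w1")
  ws <- make_windows(sig, axes = c("y", "z"), lookback = 100, hop = 100)
  expect_equal(dim(ws$x), c(3, 100, 2))
  expect_equal(unique(ws$subject_id), "w1")
  # per-window normalization: mean 0, SD 1
  expect_equal(mean(ws$x[1, , 1]), 0, tolerance = 1e-12)
  expect_equal(stats::sd(ws$x[2, , 2]), 1, tolerance = 1e-12)

  flat <- accel_signal(tibble::tibble(x = rep(1, 120), y = rep(1, 120),
                                      z = rep(1, 120)), rate = 100)
  wf <- make_windows(flat, axes = "z", lookback = 100)
  expect_false(anyNA(wf$x))
  expect_equal(max(abs(wf$x)), 0)

  short <- accel_signal(tibble::tibble(x = 1:10, y = 1:10, z = 1:10),
                        rate = 100)
  expect_warning(ws0 <- make_windows(short, lookback = 100))
  expect_equal(dim(ws0$x)[1], 0)
})

test_that("confusion metrics match brute-force arithmetic", {
  truth <- c(rep("PAD", 3), "healthy", rep("healthy", 2))
  pred <- c(rep("PAD", 3), "PAD", rep("healthy", 2))
  r <- eval_report(truth, pred)
  expect_equal(unname(r$confusion), c(3, 1, 0, 2))
  expect_equal(r$metrics[["accuracy"]], 5 / 6)
  expect_equal(r$metrics[["precision"]], 0.75)
  expect_equal(r$metrics[["recall"]], 1.0)
  expect_equal(r$metrics[["f1"]], 6 / 7)

  perfect <- eval_report(truth, truth)
  expect_equal(unname(perfect$metrics), rep(1, 4))

  none_pos <- eval_report(c("PAD", "healthy"), c("healthy", "healthy"))
  expect_true(is.na(none_pos$metrics[["precision"]]))
  expect_equal(none_pos$metrics[["recall"]], 0)

  expect_error(eval_report(character(0), character(0)),
               class = "gaitdx_data_error")

  td <- tidy(r)
  expect_equal(td$value[td$metric == "f1"], 6 / 7)
  g <- glance(r)
  expect_equal(g$tp, 3)
  # metrics recomputable from stored confusion
  m <- gaitdx:::metrics_from_confusion(g$tp, g$fp, g$fn, g$tn)
  expect_equal(unname(m), unname(r$metrics), tolerance = 1e-12)
})

test_that("window probabilities aggregate to subject labels by mean", {
  agg <- aggregate_subject(c(0.9, 0.8, 0.7), rep("s1", 3))
  expect_equal(agg$.prob, 0.8)
  expect_equal(agg$.pred, "PAD")
  one <- aggregate_subject(0.3, "s2")
  expect_equal(one$.pred, "healthy")
  tie <- aggregate_subject(c(0.5, 0.5), rep("s3", 2))
  expect_equal(tie$.pred, "PAD")  # ties classify as positive by convention
})

test_that("the RF preset builds exactly 78 stumps", {
  set.seed(1)
  data <- tibble::tibble(
    label = rep(c("healthy", "PAD"), each = 20),
    `SwingTime MV` = rnorm(40), `SwingTime SV` = rnorm(40),
    `StrideTime SV` = rnorm(40), `StepTime SA` = rnorm(40))
  m <- train_feature_model(data, "rf", seed = 3)
  expect_equal(m$fit$num.trees, 78)
  depths <- purrr::map_int(1:78, function(i) {
    info <- ranger::treeInfo(m$fit, i)
    max(0L, sum(!info$terminal))
  })
  expect_true(all(depths <= 1))
})

test_that("a separable problem is fit perfectly by the logistic model", {
  data <- tibble::tibble(
    label = rep(c("healthy", "PAD"), each = 15),
    StepTime = c(rnorm(15, 0.5, 0.01), rnorm(15, 0.8, 0.01)),
    StrideTime = c(rnorm(15, 1.0, 0.01), rnorm(15, 1.6, 0.01)))
  m <- train_feature_model(data, "logit", features = c("StepTime",
                                                       "StrideTime"))
  pred <- predict(m, data)
  expect_equal(mean(pred$.pred == data$label), 1)
  expect_true(all(pred$.prob >= 0 & pred$.prob <= 1))

  expect_error(train_feature_model(dplyr::filter(data, label == "PAD"),
                                   "logit",
                                   features = c("StepTime", "StrideTime")),
               class = "gaitdx_data_error")
})

test_that("the DNN trains and emits bounded probabilities", {
  set.seed(2)
  data <- tibble::tibble(
    label = rep(c("healthy", "PAD"), each = 20),
    StepTime = c(rnorm(20, 0.5, 0.02), rnorm(20, 0.9, 0.02)),
    StrideTime = c(rnorm(20, 1.0, 0.02), rnorm(20, 1.8, 0.02)))
  m <- train_feature_model(data, "dnn",
                           preset = list(layers = c(16, 8, 1), epochs = 150,
                                         dropout = 0.2, batch_size = 8),
                           features = c("StepTime", "StrideTime"), seed = 4)
  pred <- predict(m, data)
  expect_true(all(pred$.prob >= 0 & pred$.prob <= 1))
  expect_gte(mean(pred$.pred == data$label), 0.9)
})

test_that("sequence-model probabilities are bounded for arbitrary windows", {
  set.seed(6)
  ws <- structure(list(
    x = array(rnorm(20 * 30 * 2, sd = 5), c(20, 30, 2)),
    subject_id = rep(sprintf("s%d", 1:5), each = 4),
    label = rep(c("PAD", "healthy"), 10)), class = "window_set")
  m <- train_sequence_model(ws, preset = list(lookback = 30, epochs = 2,
                                              batch_size = 4))
  p <- predict(m, ws)
  expect_true(all(p$.prob > 0 & p$.prob < 1))
  expect_error(train_sequence_model(
    structure(list(x = array(0, c(0, 10, 2)), subject_id = character(0),
                   label = character(0)), class = "window_set")),
    class = "gaitdx_data_error")
})

test_that("model presets carry the published hyperparameters", {
  lstm <- model_preset("lstm")
  expect_equal(lstm$lookback, 100)
  expect_equal(lstm$hidden, c(4, 4))
  expect_equal(lstm$batch_size, 4)
  expect_equal(lstm$epochs, 1)
  rf <- model_preset("rf")
  expect_equal(rf$num_trees, 78)
  expect_equal(rf$max_depth, 1)
  expect_equal(rf$min_samples_leaf, 0.1585)
  expect_equal(rf$min_samples_split, 0.106)
  svm <- model_preset("svm")
  expect_equal(svm$cost, 65)
  expect_equal(svm$degree, 4)
  expect_equal(svm$kernel, "polynomial")
  dnn <- model_preset("dnn")
  expect_equal(dnn$layers, c(64, 256, 64, 1))
  expect_equal(dnn$dropout, 0.7)
  expect_equal(dnn$batch_size, 44)
})
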