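#' The seven train/test modality paths
#'
#' Catalogue of the end-to-end configurations explored by the framework:
#' raw-acceleration sequence-model paths (1-3) and extracted-feature paths
#' (4-7), each combining a training and a testing data source. Marker-derived
#' training with wearable testing (paths 2 and 7) is the deployment scenario:
#' precise laboratory data builds the model, a waist accelerometer applies it.
#'
#' @return tibble with columns `path`, `representation`, `train_modality`,
#'   `test_modality`, `features`.
#' @export
path_info <- function() {
  tibble::tribble(
    ~path, ~representation, ~train_modality, ~test_modality, ~features,
    1L, "raw",      "marker",   "marker",   NA_character_,
    2L, "raw",      "marker",   "wearable", NA_character_,
    3L, "raw",      "wearable", "wearable", NA_character_,
    4L, "features", "marker",   "marker",   "all",
    5L, "features", "marker",   "marker",   "core4",
    6L, "features", "wearable", "wearable", "core4",
    7L, "features", "marker",   "wearable", "core4"
  )
}

#' Run one train/test modality path end to end
#'
#' Splits subjects, trains the path's model on the training modality and
#' representation, and evaluates on the held-out subjects in the testing
#' modality. For raw paths the sequence model is used and test signals are
#' resampled to the training rate; for feature paths a feature classifier
#' (default: the polynomial-SVM preset) is trained on the path's feature
#' set.
#'
#' @param path path id, 1-7 (see [path_info()]).
#' @param marker_cohort,wearable_cohort cohort tibbles (`subject_id`,
#'   `label`, `signal` list-column). Marker cohorts may contain raw
#'   trajectories; they are double-differenced and filtered automatically.
#'   Only the cohorts a path needs are required.
#' @param split a [split_cohort()] result, or a named list of per-set label
#'   counts to draw one; default holds out ~30% of subjects per label.
#' @param family feature-model family for feature paths (default `"svm"`).
#' @param preset hyperparameter overrides for the path's model.
#' @param level `"subject"` or `"window"` evaluation for raw paths.
#' @param seed RNG seed controlling the split and training.
#' @return an [eval_report()] tagged with the path id.
#' @export
run_path <- function(path, marker_cohort = NULL, wearable_cohort = NULL,
                     split = NULL, family = "svm", preset = NULL,
                     level = "subject", seed = NULL) {
  info <- path_info()
  if (!path %in% info$path) {
    abort(sprintf("unknown path id %s (valid: 1-7).", path),
          class = "gaitdx_parameter_error")
  }
  info <- info[info$path == path, ]
  cohorts <- list(marker = marker_cohort, wearable = wearable_cohort)
  for (mod in unique(c(info$train_modality, info$test_modality))) {
    if (is.null(cohorts[[mod]])) {
      abort(sprintf("path %d requires a %s cohort.", path, mod),
            class = "gaitdx_data_error")
    }
  }
  cohorts$marker <- prepare_marker_cohort(cohorts$marker)

  ref <- cohorts[[info$train_modality]]
  if (!inherits(split, "split_spec")) {
    counts <- split %||% default_split_counts(ref)
    split <- split_cohort(ref, counts, seed = seed)
  }
  train_cohort <- dplyr::filter(cohorts[[info$train_modality]],
                                .data$subject_id %in% split$train)
  # cross-modality cohorts may have disjoint subject ids (different studies):
  # then every test-modality subject not seen in training is evaluated
  test_ids <- intersect(split$test %||% character(0),
                        cohorts[[info$test_modality]]$subject_id)
  if (length(test_ids) == 0) {
    test_ids <- setdiff(cohorts[[info$test_modality]]$subject_id, split$train)
  }
  test_cohort <- dplyr::filter(cohorts[[info$test_modality]],
                               .data$subject_id %in% test_ids)

  if (info$representation == "raw") {
    run_raw_path(path, train_cohort, test_cohort, preset, level, seed)
  } else {
    run_feature_path(path, info$features, train_cohort, test_cohort,
                     family, preset, seed)
  }
}

prepare_marker_cohort <- function(cohort) {
  if (is.null(cohort)) return(NULL)
  cohort$signal <- purrr::map(cohort$signal, function(sig) {
    if (inherits(sig, "marker_trajectory")) {
      butterworth_lowpass(derive_acceleration(sig))
    } else {
      sig
    }
  })
  cohort
}

default_split_counts <- function(cohort) {
  tab <- table(cohort$label)
  list(test = vapply(tab, function(n) max(1L, as.integer(round(0.3 * n))),
                     integer(1)))
}

cohort_windows <- function(cohort, preset, rate = NULL) {
  sets <- purrr::pmap(cohort, function(subject_id, label, signal, ...) {
    if (!is.null(rate) && !isTRUE(all.equal(signal_rate(signal), rate))) {
      signal <- resample_signal(signal, rate)
    }
    attr(signal, "subject_id") <- subject_id
    ws <- make_windows(signal, axes = preset$axes,
                       lookback = preset$lookback)
    ws$label <- rep(label, length(ws$subject_id))
    ws
  })
  bind_windows(sets)
}

run_raw_path <- function(path, train_cohort, test_cohort, preset, level,
                         seed) {
  preset <- utils::modifyList(model_preset("lstm"), preset %||% list())
  train_rate <- signal_rate(train_cohort$signal[[1]])
  train_w <- cohort_windows(train_cohort, preset, rate = NULL)
  test_w <- cohort_windows(test_cohort, preset, rate = train_rate)
  model <- train_sequence_model(train_w, preset = preset, seed = seed)
  evaluate_model(model, test_w, level = level, path = path)
}

run_feature_path <- function(path, features, train_cohort, test_cohort,
                             family, preset, seed) {
  subset <- feature_subset(features)
  train_f <- impute_gait_features(cohort_features(train_cohort))
  test_f <- impute_gait_features(cohort_features(test_cohort))
  model <- train_feature_model(train_f, family = family, preset = preset,
                               features = subset, seed = seed)
  evaluate_model(model, test_f, level = "subject", path = path)
}
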