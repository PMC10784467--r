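#' Subject-level train/validation/test split
#'
#' Randomly assigns subjects to sets while matching exact per-label counts,
#' so that no subject contributes data to more than one set (the unit of
#' generalization is the subject, not the window).
#'
#' @param cohort tibble with `subject_id` and `label` columns.
#' @param counts named list of per-set label counts, e.g.
#'   `list(test = c(healthy = 6, PAD = 7), validation = c(healthy = 4, PAD = 4))`.
#'   Subjects not assigned to a listed set form the training set.
#' @param seed RNG seed; the split is deterministic under it.
#' @return a `split_spec`: named list of subject-id character vectors
#'   (`train` plus the sets named in `counts`).
#' @export
split_cohort <- function(cohort, counts, seed = NULL) {
  ids <- split(cohort$subject_id, cohort$label)
  need <- purrr::map(c("healthy", "PAD"), function(lab) {
    sum(purrr::map_dbl(counts, ~ .x[[lab]] %||% 0))
  })
  names(need) <- c("healthy", "PAD")
  for (lab in names(need)) {
    if (need[[lab]] > length(ids[[lab]] %||% character(0))) {
      abort(sprintf("split requests %d %s subjects but the cohort has %d.",
                    need[[lab]], lab, length(ids[[lab]])),
            class = "gaitdx_parameter_error")
    }
  }
  with_seed(seed, {
    pool <- purrr::map(ids, sample)
    out <- list()
    for (set in names(counts)) {
      take <- character(0)
      for (lab in names(counts[[set]])) {
        k <- counts[[set]][[lab]]
        take <- c(take, pool[[lab]][seq_len(k)])
        pool[[lab]] <- pool[[lab]][-seq_len(k)]
      }
      out[[set]] <- sort(take)
    }
    out$train <- sort(unlist(pool, use.names = FALSE))
    structure(out[c("train", names(counts))], class = "split_spec")
  })
}

#' Cut an acceleration signal into fixed-length windows
#'
#' Non-overlapping (by default) windows of `lookback` samples on the chosen
#' axes, each z-normalized per axis within the window (mean 0, SD 1;
#' constant axes become zero rather than NaN). Per-window normalization
#' bridges the amplitude scales of marker-derived and wearable signals on
#' cross-modality paths.
#'
#' @param sig an [accel_signal()].
#' @param axes subset of `c("x", "y", "z")`.
#' @param lookback window length in samples (default 100).
#' @param hop stride between window starts in samples (default `lookback`).
#' @param normalize z-normalize each window per axis (default TRUE).
#' @return a `window_set`: list with array `x` (N x lookback x d), and
#'   vectors `subject_id`, `label` (label filled by the caller).
#' @export
make_windows <- function(sig, axes = c("y", "z"), lookback = 100,
                         hop = lookback, normalize = TRUE) {
  axes <- match.arg(axes, c("x", "y", "z"), several.ok = TRUE)
  n <- nrow(sig)
  if (n < lookback) {
    warn(sprintf("signal of %d samples is shorter than lookback %d; no windows.",
                 n, lookback))
    return(structure(list(x = array(0, c(0, lookback, length(axes))),
                          subject_id = character(0), label = character(0)),
                     class = "window_set"))
  }
  starts <- seq(1, n - lookback + 1, by = hop)
  x <- array(0, c(length(starts), lookback, length(axes)))
  for (j in seq_along(axes)) {
    v <- sig[[axes[j]]]
    for (i in seq_along(starts)) {
      w <- v[starts[i]:(starts[i] + lookback - 1)]
      if (normalize) {
        s <- stats::sd(w)
        w <- if (s > 0) (w - mean(w)) / s else w * 0
      }
      x[i, , j] <- w
    }
  }
  structure(list(x = x,
                 subject_id = rep(signal_subject(sig), length(starts)),
                 label = rep(NA_character_, length(starts))),
            class = "window_set")
}

#' Combine window sets
#' @param ... `window_set` objects.
#' @return a single `window_set`.
#' @export
bind_windows <- function(...) {
  sets <- list(...)
  if (length(sets) == 1 && is.list(sets[[1]]) &&
      !inherits(sets[[1]], "window_set")) {
    sets <- sets[[1]]
  }
  x <- do.call(abind3, purrr::map(sets, "x"))
  structure(list(x = x,
                 subject_id = unlist(purrr::map(sets, "subject_id")),
                 label = unlist(purrr::map(sets, "label"))),
            class = "window_set")
}

abind3 <- function(...) {
  arrs <- list(...)
  arrs <- arrs[purrr::map_int(arrs, ~ dim(.x)[1]) > 0]
  if (length(arrs) == 0) return(array(0, c(0, 0, 0)))
  d <- dim(arrs[[1]])
  out <- array(0, c(sum(purrr::map_int(arrs, ~ dim(.x)[1])), d[2], d[3]))
  at <- 0
  for (a in arrs) {
    if (dim(a)[1] > 0) out[at + seq_len(dim(a)[1]), , ] <- a
    at <- at + dim(a)[1]
  }
  out
}

#' Shipped model presets
#'
#' Fixed hyperparameter sets for each model family, as selected by the
#' original tuning study: the sequence model (2 stacked LSTM layers of 4
#' units and a sigmoid head, lookback 100, 2 axes, batch 4, Adam, 1 epoch),
#' the random forest (78 depth-1 trees, log2 feature sampling, fractional
#' leaf/split minima), the polynomial SVM (degree 4, C = 65) and the DNN
#' (layers 64-256-64-1, dropout 0.7, batch 44, sigmoid, Adam).
#'
#' @param family one of `"lstm"`, `"logit"`, `"rf"`, `"svm"`, `"dnn"`.
#' @return named list of hyperparameters.
#' @export
model_preset <- function(family = c("lstm", "logit", "rf", "svm", "dnn")) {
  family <- match.arg(family)
  switch(family,
    lstm = list(lookback = 100, axes = c("y", "z"), hidden = c(4, 4),
                batch_size = 4, epochs = 1, optimizer = "adam", lr = 1e-3),
    logit = list(feature_subset = "logit8"),
    rf = list(num_trees = 78, max_depth = 1, criterion = "gini",
              max_features = "log2", min_samples_leaf = 0.1585,
              min_samples_split = 0.106, feature_subset = "rf4"),
    svm = list(kernel = "polynomial", degree = 4, cost = 65,
               feature_subset = "all"),
    dnn = list(layers = c(64, 256, 64, 1), dropout = 0.7, batch_size = 44,
               activation = "sigmoid", optimizer = "adam", epochs = 100,
               lr = 1e-3, feature_subset = "logit8")
  )
}

#' Train a classifier on gait feature vectors
#'
#' Features are standardized with training-set means and SDs (frozen for
#' later prediction and transfer). Families: `"logit"` (binomial GLM),
#' `"rf"` (random forest of depth-limited trees), `"svm"` (polynomial-kernel
#' SVM), `"dnn"` (native multilayer perceptron).
#'
#' @param data tibble with `label` (`"PAD"`/`"healthy"`) and feature columns.
#' @param family model family.
#' @param preset hyperparameter list; defaults to [model_preset()] for the
#'   family.
#' @param features canonical subset keyword or character vector of feature
#'   names; defaults to the preset's.
#' @param seed RNG seed for stochastic trainers.
#' @return a `gait_model` object with a [predict][predict.gait_model] method.
#' @export
train_feature_model <- function(data, family = c("logit", "rf", "svm", "dnn"),
                                preset = NULL, features = NULL,
                                seed = NULL) {
  family <- match.arg(family)
  preset <- utils::modifyList(model_preset(family), preset %||% list())
  subset <- features %||% preset$feature_subset %||% "all"
  if (length(subset) == 1 && subset %in% c("all", "logit8", "rf4", "core4")) {
    subset <- feature_subset(subset)
  }
  missing_cols <- setdiff(subset, names(data))
  if (length(missing_cols) > 0) {
    abort(sprintf("data lacks feature column(s): %s",
                  paste(missing_cols, collapse = ", ")),
          class = "gaitdx_parameter_error")
  }
  if (length(unique(data$label)) < 2) {
    abort("training labels contain a single class.",
          class = "gaitdx_data_error")
  }
  X <- as.matrix(data[subset])
  center <- colMeans(X)
  scale_ <- apply(X, 2, stats::sd)
  scale_[scale_ == 0] <- 1
  Xs <- scale(X, center, scale_)
  y <- as.numeric(data$label == "PAD")

  fit <- with_seed(seed, switch(family,
    logit = {
      df <- as.data.frame(Xs)
      names(df) <- paste0("f", seq_len(ncol(df)))
      df$y <- y
      suppressWarnings(glm(y ~ ., data = df, family = binomial()))
    },
    rf = {
      df <- as.data.frame(Xs)
      names(df) <- paste0("f", seq_len(ncol(df)))
      df$y <- factor(data$label, levels = c("healthy", "PAD"))
      n <- nrow(df)
      ranger::ranger(
        y ~ ., data = df, probability = TRUE,
        num.trees = preset$num_trees, max.depth = preset$max_depth,
        mtry = max(1, floor(log2(ncol(Xs)))),
        min.node.size = max(1, ceiling(preset$min_samples_leaf * n)),
        splitrule = preset$criterion,
        seed = seed %||% sample.int(1e6, 1))
    },
    # coef0 = 1: the homogeneous (coef0 = 0) polynomial kernel is blind to
    # the sign of standardized features (K(-u, v) = K(u, v) for even degree)
    svm = e1071::svm(Xs, factor(data$label, levels = c("healthy", "PAD")),
                     kernel = preset$kernel, degree = preset$degree,
                     cost = preset$cost, coef0 = preset$coef0 %||% 1,
                     probability = TRUE, scale = FALSE),
    dnn = mlp_train(Xs, y, layers = preset$layers,
                    activation = preset$activation,
                    dropout = preset$dropout,
                    batch_size = preset$batch_size,
                    epochs = preset$epochs, lr = preset$lr, seed = seed)
  ))
  structure(list(family = family, fit = fit, features = subset,
                 center = center, scale = scale_, preset = preset,
                 threshold = 0.5),
            class = "gait_model")
}

#' Predict PAD probabilities from a fitted feature model
#'
#' @param object a `gait_model`.
#' @param newdata tibble or matrix with the model's feature columns.
#' @param ... unused.
#' @return tibble with `.prob` (probability of PAD) and `.pred` (label at
#'   the model's threshold; ties classify as PAD).
#' @export
predict.gait_model <- function(object, newdata, ...) {
  X <- as.matrix(as.data.frame(newdata)[, object$features, drop = FALSE])
  Xs <- scale(X, object$center, object$scale)
  prob <- switch(object$family,
    logit = {
      df <- as.data.frame(Xs)
      names(df) <- paste0("f", seq_len(ncol(df)))
      as.numeric(predict(object$fit, df, type = "response"))
    },
    rf = {
      df <- as.data.frame(Xs)
      names(df) <- paste0("f", seq_len(ncol(df)))
      predict(object$fit, df)$predictions[, "PAD"]
    },
    svm = {
      p <- predict(object$fit, Xs, probability = TRUE)
      list(prob = attr(p, "probabilities")[, "PAD"],
           pred = as.character(p))
    },
    dnn = mlp_predict(object$fit, Xs)
  )
  # the SVM's decision rule is used directly: Platt-scaled probabilities are
  # unreliable at small n and can disagree with the margin sign
  if (is.list(prob)) {
    tibble::tibble(.prob = as.numeric(prob$prob), .pred = prob$pred)
  } else {
    tibble::tibble(
      .prob = as.numeric(prob),
      .pred = ifelse(prob >= object$threshold, "PAD", "healthy"))
  }
}

#' Train the sequence model on raw acceleration windows
#'
#' A stacked-LSTM binary classifier trained with Adam on binary
#' cross-entropy. The shipped preset follows the tuned architecture
#' (2 LSTM layers of 4 tanh units, sigmoid output, lookback 100, batch 4,
#' 1 epoch); raise `epochs` for synthetic experiments.
#'
#' @param train a `window_set` with labels filled.
#' @param val optional validation `window_set` (monitored, not used for
#'   early stopping in the shipped preset).
#' @param preset hyperparameter list (see [model_preset()]`("lstm")`).
#' @param seed RNG seed.
#' @return a `gait_seq_model`.
#' @export
train_sequence_model <- function(train, val = NULL, preset = NULL,
                                 seed = NULL) {
  preset <- utils::modifyList(model_preset("lstm"), preset %||% list())
  if (dim(train$x)[1] == 0) {
    abort("empty training window set.", class = "gaitdx_data_error")
  }
  y <- as.numeric(train$label == "PAD")
  fit <- lstm_train(train$x, y, hidden = preset$hidden,
                    batch_size = preset$batch_size, epochs = preset$epochs,
                    lr = preset$lr, seed = seed)
  structure(list(fit = fit, preset = preset, threshold = 0.5),
            class = "gait_seq_model")
}

#' @export
predict.gait_seq_model <- function(object, newdata, ...) {
  prob <- lstm_predict(object$fit, newdata$x)
  tibble::tibble(subject_id = newdata$subject_id,
                 .prob = prob,
                 .pred = ifelse(prob >= object$threshold, "PAD", "healthy"))
}

#' Aggregate window probabilities to subject labels
#'
#' Subject score = mean window probability; the subject is classified PAD
#' iff the score reaches the threshold (ties classify as PAD).
#'
#' @param prob per-window PAD probabilities.
#' @param subject_id parallel subject ids.
#' @param threshold decision threshold (default 0.5).
#' @return tibble with `subject_id`, `.prob`, `.pred` per subject.
#' @export
aggregate_subject <- function(prob, subject_id, threshold = 0.5) {
  tibble::tibble(subject_id = subject_id, prob = prob) |>
    dplyr::group_by(.data$subject_id) |>
    dplyr::summarise(.prob = mean(.data$prob), .groups = "drop") |>
    dplyr::mutate(.pred = ifelse(.data$.prob >= threshold, "PAD", "healthy"))
}

#' Evaluate a fitted model on held-out data
#'
#' @param model a `gait_model` or `gait_seq_model`.
#' @param data feature tibble (with `label`) or labeled `window_set`.
#' @param level `"subject"` (window probabilities averaged per subject
#'   before thresholding) or `"window"`.
#' @param path optional path id tag for the report.
#' @return an [eval_report()].
#' @export
evaluate_model <- function(model, data, level = "subject", path = NA) {
  if (inherits(model, "gait_seq_model")) {
    if (dim(data$x)[1] == 0) {
      abort("empty test set.", class = "gaitdx_data_error")
    }
    pred <- predict(model, data)
    if (level == "subject") {
      agg <- aggregate_subject(pred$.prob, data$subject_id,
                               model$threshold)
      truth <- tibble::tibble(subject_id = data$subject_id,
                              label = data$label) |>
        dplyr::distinct()
      j <- dplyr::left_join(agg, truth, by = "subject_id")
      eval_report(j$label, j$.pred, level = "subject", path = path)
    } else {
      eval_report(data$label, pred$.pred, level = "window", path = path)
    }
  } else {
    pred <- predict(model, data)
    eval_report(data$label, pred$.pred, level = level, path = path)
  }
}
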