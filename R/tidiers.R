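#' Tidy an evaluation report
#'
#' @param x an [eval_report()].
#' @param ... unused.
#' @return tibble with one row per metric (`metric`, `value`).
#' @export
tidy.eval_report <- function(x, ...) {
  tibble::tibble(metric = names(x$metrics), value = as.numeric(x$metrics))
}

#' One-row summary of an evaluation report
#'
#' @param x an [eval_report()].
#' @param ... unused.
#' @return one-row tibble with confusion counts, metrics, level, path, n.
#' @export
glance.eval_report <- function(x, ...) {
  tibble::tibble(
    tp = x$confusion[["TP"]], fp = x$confusion[["FP"]],
    fn = x$confusion[["FN"]], tn = x$confusion[["TN"]],
    accuracy = x$metrics[["accuracy"]], precision = x$metrics[["precision"]],
    recall = x$metrics[["recall"]], f1 = x$metrics[["f1"]],
    level = x$level, path = x$path, n = x$n)
}

#' Tidy a fitted gait feature model
#'
#' For the logistic family the coefficient table is returned; for other
#' families, the feature list with any model-native importance available
#' (impurity importance is not computed for probability forests by default).
#'
#' @param x a `gait_model`.
#' @param ... unused.
#' @return a tibble.
#' @export
tidy.gait_model <- function(x, ...) {
  if (x$family == "logit") {
    s <- summary(x$fit)$coefficients
    tibble::tibble(
      term = c("(Intercept)", x$features)[seq_len(nrow(s))],
      estimate = s[, 1], std_error = s[, 2],
      statistic = s[, 3], p_value = s[, 4])
  } else {
    tibble::tibble(term = x$features)
  }
}

#' One-row summary of a fitted gait feature model
#'
#' @param x a `gait_model`.
#' @param ... unused.
#' @return one-row tibble with family and dimensionality.
#' @export
glance.gait_model <- function(x, ...) {
  tibble::tibble(family = x$family, n_features = length(x$features),
                 threshold = x$threshold)
}

#' Tidy a Shapley attribution result
#'
#' @param x a `shapley_result` from [shapley_rank()].
#' @param ... unused.
#' @return the ranking tibble (feature, mean absolute Shapley value).
#' @export
tidy.shapley_result <- function(x, ...) x$ranking
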