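#' Exact Shapley feature attribution by coalition enumeration
#'
#' Computes exact Shapley values for each instance in `explain` by
#' enumerating all `2^d` feature coalitions. The value of a coalition is
#' the model's mean prediction over the background set with the coalition's
#' features taken from the instance and the remaining features taken from
#' the background rows (marginalization convention). Per instance, the
#' values sum to the prediction minus the background mean prediction
#' (efficiency axiom); features the model ignores get exactly zero (dummy
#' axiom).
#'
#' @param model a `gait_model`, or a function mapping a numeric matrix of
#'   features to a numeric prediction vector.
#' @param background data frame / matrix of background rows (feature
#'   columns only, in model feature order for a bare function).
#' @param explain rows to explain (same columns).
#' @param features feature names; defaults to the model's features or the
#'   column names.
#' @return a `shapley_result`: list with `values` (instances x features
#'   matrix of Shapley values) and `ranking` (tibble of features sorted by
#'   decreasing mean absolute Shapley value).
#' @export
shapley_rank <- function(model, background, explain, features = NULL) {
  if (inherits(model, "gait_model")) {
    features <- features %||% model$features
    f <- function(X) {
      df <- as.data.frame(X)
      names(df) <- features
      predict(model, df)$.prob
    }
  } else {
    stopifnot(is.function(model))
    features <- features %||% colnames(background)
    f <- model
  }
  B <- as.matrix(as.data.frame(background)[, features, drop = FALSE])
  E <- as.matrix(as.data.frame(explain)[, features, drop = FALSE])
  d <- length(features)
  if (d > 16) {
    abort(paste0("exact enumeration is limited to 16 features (got ", d,
                 "); reduce the feature set or sample coalitions."),
          class = "gaitdx_parameter_error")
  }
  nb <- nrow(B)
  masks <- as.matrix(expand.grid(rep(list(c(FALSE, TRUE)), d)))
  sizes <- rowSums(masks)
  # Shapley kernel weights w(|S|) = |S|! (d-|S|-1)! / d!
  wt <- exp(lfactorial(0:d) + lfactorial(d - (0:d) - 1) - lfactorial(d))

  values <- matrix(0, nrow(E), d, dimnames = list(NULL, features))
  for (i in seq_len(nrow(E))) {
    x <- E[i, ]
    # v(S) for every coalition: mean prediction over background replacements
    v <- purrr::map_dbl(seq_len(nrow(masks)), function(m) {
      Xm <- B
      on <- masks[m, ]
      if (any(on)) Xm[, on] <- matrix(x[on], nb, sum(on), byrow = TRUE)
      mean(f(Xm))
    })
    key <- masks %*% (2^(seq_len(d) - 1))
    v_by_key <- numeric(2^d)
    v_by_key[key + 1] <- v
    for (j in seq_len(d)) {
      without <- !masks[, j]
      k0 <- key[without]
      k1 <- k0 + 2^(j - 1)
      values[i, j] <- sum(wt[sizes[without] + 1] *
                            (v_by_key[k1 + 1] - v_by_key[k0 + 1]))
    }
  }
  ranking <- tibble::tibble(
    feature = features,
    mean_abs_shap = unname(colMeans(abs(values)))
  ) |>
    dplyr::arrange(dplyr::desc(.data$mean_abs_shap))
  structure(list(values = values, ranking = ranking,
                 base = mean(f(B))),
            class = "shapley_result")
}

#' @export
print.shapley_result <- function(x, ...) {
  cat("<shapley_result> features by mean |Shapley value|:\n")
  print(x$ranking)
  invisible(x)
}
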