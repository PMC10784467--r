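BASE_PARAMS <- c("StepTime", "StanceTime", "StrideTime", "SwingTime")

#' The 16 canonical gait feature names
#'
#' Four base temporal parameters (per-subject means, seconds) and, for each,
#' three variability measures: magnitude of variability (MV, the standard
#' deviation over cycles), step variability (SV, the root mean of the left
#' and right per-side variances) and step asymmetry (SA, the absolute
#' difference of the per-side means).
#'
#' @return character vector of the 16 names in canonical order.
#' @export
gait_feature_names <- function() {
  c(BASE_PARAMS,
    as.vector(t(outer(BASE_PARAMS, c("MV", "SV", "SA"), paste))))
}

#' Canonical feature subsets
#'
#' @param name one of `"all"` (16 features), `"logit8"` (the eight
#'   variability/asymmetry features retained by the logistic model),
#'   `"rf4"` (the top four by mean absolute Shapley value) or `"core4"`
#'   (the four base means, the only features derivable from short wearable
#'   bouts).
#' @return character vector of feature names.
#' @export
feature_subset <- function(name = c("all", "logit8", "rf4", "core4")) {
  name <- match.arg(name)
  switch(name,
    all = gait_feature_names(),
    logit8 = c("StanceTime SV", "SwingTime SV", "StrideTime SV",
               "StepTime MV", "StepTime SA", "SwingTime SA",
               "StanceTime SA", "StrideTime SA"),
    rf4 = c("SwingTime MV", "SwingTime SV", "StrideTime SV", "StepTime SA"),
    core4 = BASE_PARAMS
  )
}

#' Per-cycle temporal gait parameters from a side-labeled event series
#'
#' For the cycle starting at the i-th initial contact: step time is the
#' interval to the next (contralateral) IC; stride time the interval to the
#' next-but-one (ipsilateral) IC; stance time runs from the IC to the
#' earliest final contact before the next-but-one IC; swing time is stride
#' minus stance. Trailing ICs lacking the required successors yield missing
#' entries. Fewer than 3 ICs give an empty table.
#'
#' @param events a `gait_events` tibble with side-labeled ICs
#'   (see [assign_sides()]).
#' @return a `gait_cycles` tibble with columns `cycle`, `side`, `step_time`,
#'   `stance_time`, `stride_time`, `swing_time` (seconds).
#' @export
extract_cycles <- function(events) {
  ic <- events[events$event == "IC", ]
  fc_times <- events$time[events$event == "FC"]
  empty <- tibble::tibble(cycle = integer(0), side = character(0),
                          step_time = numeric(0), stance_time = numeric(0),
                          stride_time = numeric(0), swing_time = numeric(0))
  class(empty) <- c("gait_cycles", class(empty))
  if (nrow(ic) < 3) return(empty)
  if (any(is.na(ic$side))) {
    abort("initial contacts must be side-labeled; run assign_sides() first.",
          class = "gaitdx_parameter_error")
  }
  n <- nrow(ic)
  t_ic <- ic$time
  rows <- purrr::map(seq_len(n), function(i) {
    step <- if (i + 1 <= n) t_ic[i + 1] - t_ic[i] else NA_real_
    stride <- if (i + 2 <= n) t_ic[i + 2] - t_ic[i] else NA_real_
    limit <- if (i + 2 <= n) t_ic[i + 2] else Inf
    cand <- fc_times[fc_times > t_ic[i] & fc_times < limit]
    stance <- if (length(cand) > 0) cand[1] - t_ic[i] else NA_real_
    tibble::tibble(cycle = i - 1L, side = ic$side[i], step_time = step,
                   stance_time = stance, stride_time = stride,
                   swing_time = stride - stance)
  })
  out <- dplyr::bind_rows(rows)
  structure(out, class = c("gait_cycles", class(out)))
}

#' The 16-feature vector of a cycle table
#'
#' Base features are means over all cycles. For each base parameter:
#' MV is the population standard deviation over all cycles pooled across
#' sides; SV is `sqrt((Var_left + Var_right) / 2)` with population
#' variances per side; SA is `|mean_left - mean_right|`. Features whose
#' prerequisites fail (no complete cycle; fewer than 2 cycles on a side for
#' SV; an empty side for SA) are emitted as missing.
#'
#' Short wearable bouts rarely contain enough consistent cycles for the
#' variability features: with `modality = "wearable"` and fewer than
#' `min_cycles_variability` complete cycles per side, only the four base
#' means are emitted and the 12 variability entries are missing.
#'
#' @param cycles a `gait_cycles` tibble from [extract_cycles()].
#' @param modality `"marker"` or `"wearable"`.
#' @param min_cycles_variability minimum complete cycles per side required
#'   to emit variability features from wearable data (default 10).
#' @return a one-row tibble with the 16 canonical feature columns; attribute
#'   `n_cycles` records how many complete cycles contributed and `core4_only`
#'   whether variability features were withheld.
#' @export
compute_gait_features <- function(cycles,
                                  modality = c("marker", "wearable"),
                                  min_cycles_variability = 10) {
  modality <- match.arg(modality)
  param_cols <- c(StepTime = "step_time", StanceTime = "stance_time",
                  StrideTime = "stride_time", SwingTime = "swing_time")
  out <- stats::setNames(rep(NA_real_, 16), gait_feature_names())

  complete <- cycles[stats::complete.cases(
    cycles[c("step_time", "stance_time", "stride_time", "swing_time")]), ]
  per_side_n <- table(factor(complete$side, levels = c("L", "R")))
  core4_only <- modality == "wearable" &&
    any(per_side_n < min_cycles_variability)

  for (param in names(param_cols)) {
    v <- cycles[[param_cols[[param]]]]
    s <- cycles$side
    ok <- !is.na(v)
    if (any(ok)) out[param] <- mean(v[ok])
    if (core4_only) next
    if (sum(ok) >= 2) out[paste(param, "MV")] <- pop_sd(v[ok])
    vl <- v[ok & s == "L"]; vr <- v[ok & s == "R"]
    if (length(vl) >= 2 && length(vr) >= 2) {
      out[paste(param, "SV")] <- sqrt((pop_var(vl) + pop_var(vr)) / 2)
    }
    if (length(vl) >= 1 && length(vr) >= 1) {
      out[paste(param, "SA")] <- abs(mean(vl) - mean(vr))
    }
  }
  if (all(is.na(out))) {
    warn("empty cycle table: all features missing.")
  }
  res <- tibble::as_tibble(as.list(out))
  structure(res, n_cycles = nrow(complete), core4_only = core4_only)
}

#' Per-subject mean imputation of a feature table
#'
#' In a table of per-subject, per-bout feature rows, each missing value is
#' replaced by the mean of that feature over the same subject's non-missing
#' rows. Values missing in all of a subject's rows stay missing and are
#' reported with a warning.
#'
#' @param features a tibble with a `subject_id` column and feature columns.
#' @param cols feature columns to impute (default: all canonical names
#'   present).
#' @return the table with missing values imputed.
#' @export
impute_gait_features <- function(features, cols = NULL) {
  cols <- cols %||% intersect(gait_feature_names(), names(features))
  out <- features |>
    dplyr::group_by(.data$subject_id) |>
    dplyr::mutate(dplyr::across(
      dplyr::all_of(cols),
      ~ ifelse(is.na(.x), mean(.x, na.rm = TRUE), .x)
    )) |>
    dplyr::ungroup()
  out[cols] <- lapply(out[cols], function(v) ifelse(is.nan(v), NA_real_, v))
  still <- vapply(out[cols], function(v) sum(is.na(v)), integer(1))
  if (any(still > 0)) {
    warn(sprintf(
      "unresolved missingness after imputation in: %s",
      paste(names(still)[still > 0], collapse = ", ")))
  }
  out
}

#' Project a feature table onto a named subset
#'
#' @param features a feature tibble (id/label columns are preserved).
#' @param subset character vector of canonical feature names, or a subset
#'   keyword accepted by [feature_subset()].
#' @return the table restricted, order-preserving, to the subset.
#' @export
select_gait_features <- function(features, subset = "all") {
  if (length(subset) == 1 &&
      subset %in% c("all", "logit8", "rf4", "core4")) {
    subset <- feature_subset(subset)
  }
  unknown <- setdiff(subset, gait_feature_names())
  if (length(unknown) > 0) {
    abort(sprintf("unknown feature name(s): %s",
                  paste(unknown, collapse = ", ")),
          class = "gaitdx_parameter_error")
  }
  keep_meta <- intersect(c("subject_id", "label", "bout"), names(features))
  features[c(keep_meta, subset)]
}

#' Full signal-to-features pipeline for one subject
#'
#' Convenience wrapper: wavelet transform of the vertical axis, event
#' detection, side assignment, cycle extraction and feature computation.
#'
#' @param sig an [accel_signal()].
#' @param scale CWT scale at the 60 Hz reference (default 10).
#' @param min_period_s minimum event separation in seconds (default 0.4).
#' @param first_side assumed side of the first step (default `"L"`).
#' @param modality passed to [compute_gait_features()]; defaults to the
#'   signal's source tag.
#' @param ... further arguments to [detect_gait_events()].
#' @return one-row feature tibble with a `subject_id` column.
#' @export
extract_gait_features <- function(sig, scale = 10, min_period_s = 0.4,
                                  first_side = "L", modality = NULL, ...) {
  modality <- modality %||%
    if (identical(signal_source(sig), "wearable")) "wearable" else "marker"
  ws <- wavelet_transform(sig, scale = scale)
  ev <- detect_gait_events(ws, min_period_s = min_period_s, ...)
  ev <- assign_sides(ev, first_side)
  feats <- compute_gait_features(extract_cycles(ev), modality = modality)
  dplyr::bind_cols(tibble::tibble(subject_id = signal_subject(sig)), feats)
}

#' Feature table for a whole cohort
#'
#' Maps [extract_gait_features()] over a cohort tibble (as returned by
#' [load_cohort()] or [simulate_cohort()] after modality selection).
#'
#' @param cohort tibble with `subject_id`, `label` and a `signal` list-column
#'   of acceleration signals.
#' @param ... passed to [extract_gait_features()].
#' @return feature tibble, one row per subject, with `subject_id` and
#'   `label`.
#' @export
cohort_features <- function(cohort, ...) {
  rows <- purrr::map2(cohort$signal, cohort$subject_id, function(sig, id) {
    attr(sig, "subject_id") <- id
    extract_gait_features(sig, ...)
  })
  dplyr::bind_cols(
    tibble::tibble(subject_id = cohort$subject_id, label = cohort$label),
    dplyr::bind_rows(rows)[gait_feature_names()]
  )
}
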