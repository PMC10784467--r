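#' Read a marker-trajectory CSV
#'
#' Expects a comma-separated file with one header row and columns `x`, `y`,
#' `z` (a `time` column is accepted and ignored in favour of the stated
#' rate). Axis convention: x anterior-posterior, y mediolateral, z vertical;
#' use `col_map` to read files with other column names.
#'
#' @param path CSV file path.
#' @param units `"m"` or `"mm"`; positions are converted to meters.
#' @param rate sampling rate in Hz.
#' @param subject_id optional subject identifier.
#' @param col_map optional named character vector mapping canonical names to
#'   file columns, e.g. `c(x = "AP", y = "ML", z = "VT")`.
#' @return a [marker_trajectory()].
#' @export
read_marker_csv <- function(path, units = c("m", "mm"), rate = 60,
                            subject_id = NA_character_, col_map = NULL) {
  units <- match.arg(units)
  df <- read_signal_table(path, col_map)
  scale <- if (units == "mm") 1e-3 else 1
  marker_trajectory(
    dplyr::mutate(df, dplyr::across(c("x", "y", "z"), ~ .x * scale)),
    rate = rate, subject_id = subject_id
  )
}

#' Read a wearable-accelerometer CSV
#'
#' Reads an ActiGraph-style CSV export (comma separated, one header row,
#' columns `x`, `y`, `z`; any leading meta lines must already be stripped).
#'
#' @inheritParams read_marker_csv
#' @param units `"m/s2"` or `"g"`; accelerations are converted to m/s^2
#'   (1 g = 9.80665 m/s^2).
#' @param rate sampling rate in Hz (100 for the ActiGraph protocol).
#' @return an [accel_signal()] tagged `"wearable"`.
#' @export
read_accel_csv <- function(path, units = c("m/s2", "g"), rate = 100,
                           subject_id = NA_character_, col_map = NULL) {
  units <- match.arg(units)
  df <- read_signal_table(path, col_map, min_rows = 1)
  scale <- if (units == "g") GRAVITY_MS2 else 1
  accel_signal(
    dplyr::mutate(df, dplyr::across(c("x", "y", "z"), ~ .x * scale)),
    rate = rate, source = "wearable", subject_id = subject_id
  )
}

read_signal_table <- function(path, col_map = NULL, min_rows = 3) {
  if (!file.exists(path)) {
    abort(sprintf("file not found: %s", path), class = "gaitdx_io_error")
  }
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (!is.null(col_map)) {
    for (canon in names(col_map)) {
      if (!col_map[[canon]] %in% names(df)) {
        abort(sprintf("mapped column \"%s\" not found in %s",
                      col_map[[canon]], path),
              class = "gaitdx_format_error")
      }
      names(df)[names(df) == col_map[[canon]]] <- canon
    }
  }
  missing_cols <- setdiff(c("x", "y", "z"), names(df))
  if (length(missing_cols) > 0) {
    abort(sprintf("%s is missing column(s): %s", path,
                  paste(missing_cols, collapse = ", ")),
          class = "gaitdx_format_error")
  }
  if (nrow(df) < min_rows) {
    abort(sprintf("%s has %d data rows; at least %d required.",
                  path, nrow(df), min_rows),
          class = "gaitdx_insufficient_data_error")
  }
  for (axis in c("x", "y", "z")) {
    v <- df[[axis]]
    if (!is.numeric(v)) {
      bad <- which(is.na(suppressWarnings(as.numeric(v))) & !is.na(v))
      abort(sprintf("non-numeric value in column \"%s\" of %s (data row %s)",
                    axis, path,
                    if (length(bad)) bad[1] else "?"),
            class = "gaitdx_parse_error")
    }
  }
  df[c("x", "y", "z")]
}

#' Write a signal object to CSV
#'
#' Writes `time`, `x`, `y`, `z` in SI units (meters or m/s^2). Reading the
#' file back with the matching reader at `units = "m"` / `"m/s2"` reproduces
#' the numeric columns exactly (round-trip property).
#'
#' @param sig a `marker_trajectory` or `accel_signal`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_signal_csv <- function(sig, path) {
  readr::write_csv(tibble::as_tibble(sig)[c("time", "x", "y", "z")], path)
  invisible(path)
}

#' Read a cohort manifest
#'
#' A manifest is a CSV with columns `subject_id`, `label` (`PAD`/`healthy`),
#' `modality` (`marker`/`wearable`), `path` (relative to the manifest file),
#' `units` and `rate`.
#'
#' @param path manifest CSV path.
#' @return a tibble, one row per subject file.
#' @export
read_cohort_manifest <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  required <- c("subject_id", "label", "modality", "path", "units", "rate")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0) {
    abort(sprintf("manifest is missing column(s): %s",
                  paste(missing_cols, collapse = ", ")),
          class = "gaitdx_manifest_error")
  }
  df$path <- file.path(dirname(path), df$path)
  validate_manifest(df)
}

validate_manifest <- function(manifest) {
  manifest <- tibble::as_tibble(manifest)
  dup <- manifest$subject_id[duplicated(manifest$subject_id)]
  if (length(dup) > 0) {
    abort(sprintf("duplicate subject_id in manifest: %s",
                  paste(unique(dup), collapse = ", ")),
          class = "gaitdx_manifest_error")
  }
  bad_label <- setdiff(unique(manifest$label), c("PAD", "healthy"))
  if (length(bad_label) > 0) {
    abort(sprintf("unknown label(s): %s", paste(bad_label, collapse = ", ")),
          class = "gaitdx_manifest_error")
  }
  bad_mod <- setdiff(unique(manifest$modality), c("marker", "wearable"))
  if (length(bad_mod) > 0) {
    abort(sprintf("unknown modality: %s", paste(bad_mod, collapse = ", ")),
          class = "gaitdx_manifest_error")
  }
  if (any(manifest$rate <= 0)) {
    abort("manifest rates must be positive.", class = "gaitdx_manifest_error")
  }
  manifest
}

#' Load a cohort from a manifest
#'
#' Reads every file referenced by the manifest into the shared data model.
#' Per-file failures are collected and reported together with the offending
#' `subject_id`s.
#'
#' @param manifest a manifest tibble ([read_cohort_manifest()]) or path to one.
#' @return a cohort tibble with columns `subject_id`, `label`, `modality` and
#'   a `signal` list-column of [marker_trajectory()] / [accel_signal()]
#'   objects.
#' @export
load_cohort <- function(manifest) {
  if (is.character(manifest)) manifest <- read_cohort_manifest(manifest)
  manifest <- validate_manifest(manifest)
  rows <- purrr::pmap(manifest, function(subject_id, label, modality, path,
                                         units, rate, ...) {
    sig <- tryCatch(
      if (modality == "marker") {
        read_marker_csv(path, units = units, rate = rate,
                        subject_id = subject_id)
      } else {
        read_accel_csv(path, units = units, rate = rate,
                       subject_id = subject_id)
      },
      error = function(e) e
    )
    list(subject_id = subject_id, label = label, modality = modality,
         signal = sig)
  })
  failed <- purrr::keep(rows, ~ inherits(.x$signal, "error"))
  if (length(failed) > 0) {
    msgs <- purrr::map_chr(failed,
                           ~ sprintf("%s: %s", .x$subject_id,
                                     conditionMessage(.x$signal)))
    abort(paste0("failed to load ", length(failed), " subject(s):\n",
                 paste(msgs, collapse = "\n")),
          class = "gaitdx_load_error")
  }
  tibble::tibble(
    subject_id = purrr::map_chr(rows, "subject_id"),
    label = purrr::map_chr(rows, "label"),
    modality = purrr::map_chr(rows, "modality"),
    signal = purrr::map(rows, "signal")
  )
}
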