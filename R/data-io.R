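# Subject-level and aggregated data models, file schemas, validation.

# Event coding used throughout: 0 = censored, 1 = AE of interest, 2 = competing event.
EVENT_CENSORED <- 0L
EVENT_AE <- 1L
EVENT_CE <- 2L

AGGREGATE_SCHEMA_VERSION <- "aerisk-aggregate-v1"
AGGREGATE_COLUMNS <- c(
  "trial_id", "ae_id", "arm", "estimator", "tau", "estimate", "variance",
  "n", "d_ae", "d_ce", "n_cens", "person_time"
)

#' Construct a subject-level trial dataset
#'
#' A `trial_data` object is a tibble of time-to-first-event records, one row
#' per subject, carrying the trial and adverse-event identifiers as
#' attributes. Each record holds the time from randomization to the first of:
#' the AE of interest (`event_code = 1`), a competing event that precludes
#' observation of the AE (`event_code = 2`, e.g. death before AE), or
#' censoring (`event_code = 0`). One dataset describes one AE type.
#'
#' @param x A data frame with columns `subject_id`, `arm`, `time`,
#'   `event_code`. Times are positive reals on an arbitrary scale (days by
#'   convention); `event_code` must be 0 (censored), 1 (AE) or 2 (competing
#'   event); `subject_id` must be unique.
#' @param trial_id,ae_id Identifier strings attached to the dataset.
#' @return A tibble of class `trial_data`.
#' @examples
#' toy <- trial_data(data.frame(
#'   subject_id = paste0("s", 1:4), arm = "experimental",
#'   time = 1:4, event_code = c(1, 2, 0, 1)
#' ))
#' max_eval_time(toy)
#' @export
trial_data <- function(x, trial_id = "trial", ae_id = "ae") {
  x <- tibble::as_tibble(x)
  validate_trial_records(x)
  out <- dplyr::mutate(
    x,
    subject_id = as.character(.data$subject_id),
    arm = as.character(.data$arm),
    time = as.numeric(.data$time),
    event_code = as.integer(.data$event_code)
  )
  structure(out,
    class = c("trial_data", class(out)),
    trial_id = as.character(trial_id), ae_id = as.character(ae_id)
  )
}

#' @export
print.trial_data <- function(x, ...) {
  cat(sprintf(
    "<trial_data> trial '%s', AE '%s': %d subjects, arms: %s\n",
    trial_id(x), ae_id(x), nrow(x), paste(sort(unique(x$arm)), collapse = ", ")
  ))
  NextMethod()
}

#' @rdname trial_data
#' @export
trial_id <- function(x) attr(x, "trial_id") %||% "trial"

#' @rdname trial_data
#' @export
ae_id <- function(x) attr(x, "ae_id") %||% "ae"

validate_trial_records <- function(x, file = NULL) {
  required <- c("subject_id", "arm", "time", "event_code")
  missing_cols <- setdiff(required, names(x))
  if (length(missing_cols) > 0) {
    abort(sprintf(
      "Schema error%s: missing column(s) %s.",
      if (is.null(file)) "" else paste0(" in '", file, "'"),
      paste0("'", missing_cols, "'", collapse = ", ")
    ), class = "aerisk_schema_error")
  }
  if (nrow(x) == 0) {
    abort("A trial dataset must contain at least one subject record.",
      class = "aerisk_validation_error"
    )
  }
  time <- suppressWarnings(as.numeric(x$time))
  bad_time <- which(is.na(time) | !is.finite(time) | time <= 0)
  code <- suppressWarnings(as.integer(x$event_code))
  bad_code <- which(is.na(code) | !code %in% c(EVENT_CENSORED, EVENT_AE, EVENT_CE))
  dup <- which(duplicated(x$subject_id))
  problems <- character(0)
  if (length(bad_time) > 0) {
    problems <- c(problems, sprintf(
      "nonpositive/missing time in row(s) %s (subject(s) %s)",
      paste(bad_time, collapse = ", "),
      paste(x$subject_id[bad_time], collapse = ", ")
    ))
  }
  if (length(bad_code) > 0) {
    problems <- c(problems, sprintf(
      "event_code outside {0, 1, 2} in row(s) %s (subject(s) %s)",
      paste(bad_code, collapse = ", "),
      paste(x$subject_id[bad_code], collapse = ", ")
    ))
  }
  if (length(dup) > 0) {
    problems <- c(problems, sprintf(
      "duplicated subject_id in row(s) %s (%s)",
      paste(dup, collapse = ", "),
      paste(unique(x$subject_id[dup]), collapse = ", ")
    ))
  }
  if (length(problems) > 0) {
    abort(paste0("Invalid trial records: ", paste(problems, collapse = "; "), "."),
      class = "aerisk_validation_error"
    )
  }
  invisible(x)
}

#' Read a subject-level trial CSV
#'
#' Expects a comma-separated file (UTF-8, '.' decimal) with header columns
#' `subject_id`, `arm`, `time`, `event_code` and, optionally, `ce_subtype`.
#' Rows violating the record invariants (positive finite time, event code in
#' \{0, 1, 2\}, unique subject ids) are reported with their row numbers.
#'
#' @inheritParams trial_data
#' @param path Path to the CSV file.
#' @param ce_death_only If `TRUE`, apply the "death only as competing event"
#'   sensitivity recoding at load time: competing-event rows whose
#'   `ce_subtype` is not `"death"` are recoded as censored. Requires a
#'   `ce_subtype` column.
#' @return A [trial_data] tibble.
#' @export
read_trial <- function(path, trial_id = NULL, ae_id = NULL, ce_death_only = FALSE) {
  x <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  validate_trial_records(x, file = path)
  if (isTRUE(ce_death_only)) {
    if (!"ce_subtype" %in% names(x)) {
      abort("`ce_death_only = TRUE` requires a `ce_subtype` column.",
        class = "aerisk_schema_error"
      )
    }
    x <- dplyr::mutate(x, event_code = dplyr::if_else(
      .data$event_code == EVENT_CE & .data$ce_subtype != "death",
      EVENT_CENSORED, as.integer(.data$event_code)
    ))
  }
  trial_data(x,
    trial_id = trial_id %||% tools::file_path_sans_ext(basename(path)),
    ae_id = ae_id %||% "ae"
  )
}

#' Maximal evaluation time of a dataset
#'
#' The latest time at which the dataset has an observation — event or
#' censored — pooled over arms. This is the default evaluation time \eqn{\tau}
#' at which AE probabilities are read off. For an arm-wise variant, filter the
#' dataset to one arm first.
#'
#' @param data A [trial_data] tibble (any data frame with a `time` column
#'   works).
#' @return A positive scalar.
#' @export
max_eval_time <- function(data) {
  if (is.null(data) || nrow(data) == 0) {
    abort("Cannot compute the maximal evaluation time of an empty dataset.",
      class = "aerisk_validation_error"
    )
  }
  max(data$time)
}

# Filter records to one arm, with informative errors. `arm = NULL` is allowed
# only for single-arm datasets.
arm_records <- function(data, arm = NULL) {
  arms <- unique(data$arm)
  if (is.null(arm)) {
    if (length(arms) > 1) {
      abort(sprintf(
        "Dataset has arms %s; specify `arm`.",
        paste0("'", arms, "'", collapse = ", ")
      ))
    }
    return(data)
  }
  out <- data[data$arm == arm, , drop = FALSE]
  if (nrow(out) == 0) {
    abort(sprintf("Arm '%s' is empty or absent.", arm),
      class = "aerisk_validation_error"
    )
  }
  out
}

# The two arm labels of a comparative dataset, experimental first.
comparison_arms <- function(data, experimental = NULL, control = NULL) {
  arms <- sort(unique(data$arm))
  if (is.null(experimental) && is.null(control)) {
    if (all(c("experimental", "control") %in% arms)) {
      return(c(experimental = "experimental", control = "control"))
    }
    if (length(arms) == 2) {
      # alphabetical fallback: first label is taken as control
      return(c(experimental = arms[2], control = arms[1]))
    }
    abort("Comparative estimators need a dataset with exactly two arms (or explicit `experimental`/`control` labels).")
  }
  if (is.null(experimental)) experimental <- setdiff(arms, control)
  if (is.null(control)) control <- setdiff(arms, experimental)
  if (length(experimental) != 1 || length(control) != 1) {
    abort("Could not resolve a unique experimental/control arm pair.")
  }
  c(experimental = experimental, control = control)
}

#' Aggregated summaries: the shareable schema
#'
#' Aggregated summaries carry, per (trial, AE, arm, estimator), the point
#' estimate at the evaluation time with its variance and the event counts —
#' and nothing subject-level. This is the unit of exchange for federated
#' meta-analysis: individual organizations run the estimators locally and
#' forward only these rows.
#'
#' `as_aggregate()` converts rows produced by the absolute-risk estimators
#' (see [estimate_ae_risk()]) into the schema; `write_aggregate()` and
#' `read_aggregate()` give a lossless, versioned CSV round trip.
#' `write_aggregate()` refuses any input containing subject-level fields
#' (`subject_id`, `event_code`, or per-subject `time`), enforcing the privacy
#' contract.
#'
#' @param estimates A tibble of absolute-risk estimates.
#' @param trial_id,ae_id Identifiers; defaults are taken from attributes when
#'   present.
#' @return A tibble with columns `trial_id`, `ae_id`, `arm`, `estimator`,
#'   `tau`, `estimate`, `variance`, `n`, `d_ae`, `d_ce`, `n_cens`,
#'   `person_time`.
#' @export
as_aggregate <- function(estimates, trial_id = NULL, ae_id = NULL) {
  trial_id <- trial_id %||% attr(estimates, "trial_id") %||% "trial"
  ae_id <- ae_id %||% attr(estimates, "ae_id") %||% "ae"
  needed <- setdiff(AGGREGATE_COLUMNS, c("trial_id", "ae_id"))
  missing_cols <- setdiff(needed, names(estimates))
  if (length(missing_cols) > 0) {
    abort(sprintf(
      "Estimates lack column(s) %s required by the aggregate schema.",
      paste0("'", missing_cols, "'", collapse = ", ")
    ), class = "aerisk_schema_error")
  }
  out <- dplyr::bind_cols(
    tibble::tibble(trial_id = trial_id, ae_id = ae_id),
    estimates[needed]
  )
  validate_aggregate(out)
  out
}

validate_aggregate <- function(x) {
  missing_cols <- setdiff(AGGREGATE_COLUMNS, names(x))
  if (length(missing_cols) > 0) {
    abort(sprintf(
      "Aggregate summary lacks column(s) %s.",
      paste0("'", missing_cols, "'", collapse = ", ")
    ), class = "aerisk_schema_error")
  }
  if (nrow(x) > 0) {
    if (any(x$estimate < 0 | x$estimate > 1, na.rm = TRUE)) {
      abort("Aggregate estimates must lie in [0, 1].", class = "aerisk_validation_error")
    }
    if (any(x$variance < 0, na.rm = TRUE)) {
      abort("Aggregate variances must be nonnegative.", class = "aerisk_validation_error")
    }
  }
  invisible(x)
}

#' @rdname as_aggregate
#' @param x An aggregate summary tibble.
#' @param path CSV path.
#' @export
write_aggregate <- function(x, path) {
  forbidden <- intersect(c("subject_id", "event_code"), names(x))
  if (length(forbidden) > 0) {
    abort(sprintf(
      "Refusing to write subject-level field(s) %s through the aggregated-summary path.",
      paste0("'", forbidden, "'", collapse = ", ")
    ), class = "aerisk_privacy_error")
  }
  validate_aggregate(x)
  body <- readr::format_csv(x[AGGREGATE_COLUMNS])
  # format_csv terminates its own lines; the schema comment needs an explicit one
  writeLines(c(paste0("# ", AGGREGATE_SCHEMA_VERSION, "\n"), body), path, sep = "")
  invisible(path)
}

#' @rdname as_aggregate
#' @export
read_aggregate <- function(path) {
  first <- readLines(path, n = 1)
  if (!startsWith(first, "#")) {
    warn("Aggregate file carries no schema-version line; assuming current schema.")
  }
  x <- readr::read_csv(path,
    comment = "#", show_col_types = FALSE, progress = FALSE,
    col_types = readr::cols(
      trial_id = readr::col_character(), ae_id = readr::col_character(),
      arm = readr::col_character(), estimator = readr::col_character(),
      .default = readr::col_double()
    )
  )
  x <- dplyr::mutate(x, dplyr::across(c("n", "d_ae", "d_ce", "n_cens"), as.integer))
  validate_aggregate(x)
  x
}

`%||%` <- function(a, b) if (is.null(a)) b else a
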