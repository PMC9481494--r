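#' Validate a trial-level response table
#'
#' Checks a tibble of trial-level 3AFC sound-localization responses against
#' the schema used throughout the package: one row per trial with columns
#' `participant_id`, `ethnicity`, `condition`, `trial_type`, `azimuth_deg`,
#' `response` and `vigilance_correct`. Experimental trials must have an
#' azimuth on the standard nine-location grid (see [design_azimuths()]), a
#' left/middle/right response, and no vigilance flag; vigilance trials must
#' carry `vigilance_correct`; `ethnicity` must be constant within a
#' participant.
#'
#' @param trials A data frame of trials.
#' @param strict If `TRUE` (default) any violation aborts with an
#'   informative error; if `FALSE`, offending rows are dropped with a
#'   message giving the count.
#' @return A validated tibble (invisibly identical to the input when all
#'   rows pass). The number of dropped rows is attached as attribute
#'   `"n_dropped"`.
#' @export
validate_trials <- function(trials, strict = TRUE) {
  required <- c("participant_id", "condition", "trial_type", "azimuth_deg",
                "response", "vigilance_correct")
  missing_cols <- setdiff(required, names(trials))
  if (length(missing_cols) > 0) {
    abort(paste0("trial table is missing required column(s): ",
                 paste(missing_cols, collapse = ", ")),
          class = "gazecone_schema_error")
  }
  trials <- tibble::as_tibble(trials)
  if (!"ethnicity" %in% names(trials)) trials$ethnicity <- NA_character_
  trials$participant_id <- as.character(trials$participant_id)
  trials$azimuth_deg <- as.numeric(trials$azimuth_deg)
  trials$vigilance_correct <- as.logical(trials$vigilance_correct)

  bad_enum <- function(x, allowed) !is.na(x) & !(x %in% allowed)

  is_exp <- trials$trial_type == "experimental"
  problems <- list(
    unknown_trial_type = bad_enum(trials$trial_type, TRIAL_TYPES) |
      is.na(trials$trial_type),
    unknown_condition = bad_enum(trials$condition, CONDITIONS) |
      (is_exp & is.na(trials$condition)),
    unknown_response = bad_enum(trials$response, RESPONSES) |
      (is_exp & is.na(trials$response)),
    unknown_ethnicity = bad_enum(trials$ethnicity, ETHNICITIES),
    off_grid_azimuth = is_exp &
      (is.na(trials$azimuth_deg) | !(trials$azimuth_deg %in% DESIGN_AZIMUTHS)),
    vigilance_flag_on_experimental = is_exp & !is.na(trials$vigilance_correct),
    vigilance_flag_missing = !is_exp & !is.na(trials$trial_type) &
      is.na(trials$vigilance_correct)
  )
  # replace NA comparisons introduced by NA trial_type
  problems <- lapply(problems, function(p) { p[is.na(p)] <- TRUE; p })
  bad <- Reduce(`|`, problems)

  if (any(bad)) {
    labels <- names(problems)[vapply(problems, any, logical(1))]
    msg <- paste0(sum(bad), " row(s) violate the trial schema (",
                  paste(labels, collapse = ", "),
                  "); first offending row: ", which(bad)[1])
    if (strict) {
      cls <- if (any(problems$unknown_condition | problems$unknown_response |
                       problems$unknown_trial_type | problems$unknown_ethnicity)) {
        "gazecone_value_error"
      } else {
        "gazecone_schema_error"
      }
      abort(msg, class = cls)
    }
    inform(paste0("dropping ", msg))
    trials <- trials[!bad, , drop = FALSE]
  }

  eth <- dplyr::summarise(
    dplyr::group_by(trials, .data$participant_id),
    n_eth = dplyr::n_distinct(.data$ethnicity, na.rm = FALSE),
    .groups = "drop"
  )
  if (any(eth$n_eth > 1)) {
    offenders <- eth$participant_id[eth$n_eth > 1]
    msg <- paste0("ethnicity varies within participant(s): ",
                  paste(offenders, collapse = ", "))
    if (strict) abort(msg, class = "gazecone_schema_error")
    inform(paste0("dropping all rows of ", length(offenders),
                  " participant(s) with inconsistent ethnicity"))
    trials <- trials[!(trials$participant_id %in% offenders), , drop = FALSE]
  }

  n_dropped <- sum(bad)
  attr(trials, "n_dropped") <- n_dropped
  trials
}

#' Read trial-level responses from CSV
#'
#' Reads a comma-separated, UTF-8 trial table with one header row into the
#' package's trial schema and validates it (see [validate_trials()]).
#' Empty `vigilance_correct` cells (experimental trials) become `NA`.
#'
#' @param path Path to a CSV file.
#' @inheritParams validate_trials
#' @return A tibble of trials.
#' @export
read_trials <- function(path, strict = TRUE) {
  if (!file.exists(path)) {
    abort(paste0("trial file not found: ", path), class = "gazecone_io_error")
  }
  trials <- readr::read_csv(
    path,
    col_types = readr::cols(
      participant_id = readr::col_character(),
      ethnicity = readr::col_character(),
      condition = readr::col_character(),
      trial_type = readr::col_character(),
      azimuth_deg = readr::col_double(),
      response = readr::col_character(),
      vigilance_correct = readr::col_logical(),
      .default = readr::col_character()
    ),
    na = c("", "NA"),
    progress = FALSE, show_col_types = FALSE
  )
  validate_trials(trials, strict = strict)
}

#' Write trial-level responses to CSV
#'
#' Inverse of [read_trials()]: `read_trials(write_trials(x, p))` reproduces
#' `x`. Missing values (e.g. `vigilance_correct` on experimental trials)
#' are written as empty cells.
#'
#' @param trials A validated tibble of trials.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_trials <- function(trials, path) {
  trials <- validate_trials(trials, strict = TRUE)
  cols <- c("participant_id", "ethnicity", "condition", "trial_type",
            "azimuth_deg", "response", "vigilance_correct")
  readr::write_csv(trials[, cols], path, na = "", progress = FALSE)
  invisible(path)
}

#' Aggregate trials to per-azimuth response counts
#'
#' Collapses experimental trials to one row per participant, condition and
#' azimuth with the number of left, middle and right responses. Vigilance
#' trials are ignored. Azimuths of the standard grid with no trials for a
#' participant-condition become zero-count rows flagged `complete = FALSE`,
#' so downstream fitting preconditions, not IO, decide what to reject.
#'
#' @param trials A tibble of trials (experimental rows are selected
#'   internally).
#' @return A tibble with columns `participant_id`, `ethnicity`,
#'   `condition`, `azimuth_deg`, `n_left`, `n_middle`, `n_right`,
#'   `n_total`, `complete`.
#' @export
#' @examples
#' cohort <- simulate_cohort(cohort_spec(n_participants = c(white = 2), seed = 1))
#' aggregate_counts(cohort$trials)
aggregate_counts <- function(trials) {
  exp_trials <- dplyr::filter(trials, .data$trial_type == "experimental")
  if (nrow(exp_trials) == 0) {
    return(tibble::tibble(
      participant_id = character(), ethnicity = character(),
      condition = character(), azimuth_deg = numeric(),
      n_left = integer(), n_middle = integer(), n_right = integer(),
      n_total = integer(), complete = logical()
    ))
  }
  eth <- dplyr::distinct(exp_trials, .data$participant_id, .data$ethnicity)
  counts <- exp_trials |>
    dplyr::count(.data$participant_id, .data$condition, .data$azimuth_deg,
                 .data$response) |>
    tidyr::pivot_wider(names_from = "response", values_from = "n",
                       values_fill = 0L, names_prefix = "n_")
  for (col in paste0("n_", RESPONSES)) {
    if (!col %in% names(counts)) counts[[col]] <- 0L
  }
  counts <- counts |>
    tidyr::complete(
      tidyr::nesting(participant_id, condition),
      azimuth_deg = DESIGN_AZIMUTHS,
      fill = list(n_left = 0L, n_middle = 0L, n_right = 0L)
    ) |>
    dplyr::mutate(n_total = .data$n_left + .data$n_middle + .data$n_right,
                  complete = .data$n_total > 0L) |>
    dplyr::left_join(eth, by = "participant_id") |>
    dplyr::select("participant_id", "ethnicity", "condition", "azimuth_deg",
                  "n_left", "n_middle", "n_right", "n_total", "complete") |>
    dplyr::arrange(.data$participant_id, .data$condition, .data$azimuth_deg)
  counts
}
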