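#' Vigilance (catch-trial) check
#'
#' Computes each participant's vigilance failure rate and flags those who
#' failed more than `threshold` (default 20%) of their catch trials — a
#' strict inequality, so a participant at exactly the threshold is
#' retained.
#'
#' @param trials Trial tibble containing vigilance rows for every
#'   participant.
#' @param threshold Failure-rate cutoff; flag when rate is strictly above.
#' @return Tibble: `participant_id`, `n_vigilance`, `n_failed`,
#'   `vigilance_fail_rate`, `vigilance_flag`.
#' @export
vigilance_check <- function(trials, threshold = 0.2) {
  vig <- dplyr::filter(trials, .data$trial_type != "experimental")
  all_ids <- unique(trials$participant_id)
  missing <- setdiff(all_ids, unique(vig$participant_id))
  if (length(missing) > 0) {
    abort(paste0("participant(s) without vigilance trials: ",
                 paste(missing, collapse = ", ")),
          class = "gazecone_data_error")
  }
  vig |>
    dplyr::group_by(.data$participant_id) |>
    dplyr::summarise(
      n_vigilance = dplyr::n(),
      n_failed = sum(!.data$vigilance_correct),
      vigilance_fail_rate = .data$n_failed / .data$n_vigilance,
      .groups = "drop"
    ) |>
    dplyr::mutate(vigilance_flag = .data$vigilance_fail_rate > threshold)
}

#' Edge-accuracy check at the easiest azimuths
#'
#' At -40 and +40 degrees the correct side is unambiguous, so accuracy
#' there is a data-quality probe: at -40 the "left" response counts as
#' correct, at +40 "right" does, and "middle" is incorrect. A participant
#' is flagged when accuracy at any condition-edge combination falls
#' strictly below `threshold` (default 80%); with `pooled = TRUE` counts
#' are pooled over conditions before the comparison.
#'
#' @param counts Output of [aggregate_counts()] including the edge rows.
#' @param threshold Accuracy cutoff; flag when strictly below.
#' @param pooled Pool counts across conditions per edge before comparing.
#' @return Tibble with one row per participant, condition (or `"pooled"`)
#'   and edge: `azimuth_deg`, `accuracy`, plus a per-participant
#'   `edge_flag`.
#' @export
edge_accuracy_check <- function(counts, threshold = 0.8, pooled = FALSE) {
  edges <- dplyr::filter(counts, .data$azimuth_deg %in% c(-40, 40))
  have <- edges |>
    dplyr::group_by(.data$participant_id, .data$condition) |>
    dplyr::summarise(n_edges = sum(.data$n_total > 0), .groups = "drop")
  if (nrow(edges) == 0 || any(have$n_edges < 2)) {
    abort("edge azimuths (-40, +40) missing for some participant-condition",
          class = "gazecone_data_error")
  }
  if (pooled) {
    edges <- edges |>
      dplyr::group_by(.data$participant_id, .data$azimuth_deg) |>
      dplyr::summarise(dplyr::across(dplyr::starts_with("n_"), sum),
                       .groups = "drop") |>
      dplyr::mutate(condition = "pooled")
  }
  acc <- edges |>
    dplyr::mutate(accuracy = dplyr::if_else(
      .data$azimuth_deg < 0,
      .data$n_left / .data$n_total,
      .data$n_right / .data$n_total
    )) |>
    dplyr::select("participant_id", "condition", "azimuth_deg", "accuracy")
  acc |>
    dplyr::group_by(.data$participant_id) |>
    dplyr::mutate(edge_flag = any(.data$accuracy < threshold)) |>
    dplyr::ungroup()
}

#' Apply the participant-exclusion rules
#'
#' Applies, in order, the vigilance check (> 20% failed catch trials), the
#' edge-accuracy check (< 80% correct at an easiest azimuth), and the
#' fit-failure check (cone width undefined in any condition). Behavioural
#' checks are evaluated for everyone; the fits are run only for
#' participants who survive them, mirroring the sequential accounting of
#' exclusions in studies of this kind, and saving pointless fits of
#' degenerate responders. Flagged participants are removed wholesale (all
#' conditions).
#'
#' @param trials Trial tibble for the full cohort.
#' @param widths Optional precomputed [cone_widths()] table; when `NULL`
#'   the fits are run here on the behaviourally retained participants.
#' @param vigilance_threshold,edge_threshold QC cutoffs (strict
#'   inequalities).
#' @param pooled_edges Pool edge accuracy across conditions.
#' @param control [fit_control()] used when fitting internally.
#' @return A list:
#'   \describe{
#'     \item{trials}{retained trials,}
#'     \item{widths}{cone widths of retained participants,}
#'     \item{report}{one row per participant: `vigilance_fail_rate`,
#'       `min_edge_accuracy`, `fit_ok`, `excluded`, and `reasons`, a
#'       comma-separated subset of `vigilance`, `edge_accuracy`,
#'       `fit_failure` (empty iff retained).}
#'   }
#' @export
apply_exclusions <- function(trials, widths = NULL,
                             vigilance_threshold = 0.2,
                             edge_threshold = 0.8,
                             pooled_edges = FALSE,
                             control = fit_control()) {
  vig <- vigilance_check(trials, threshold = vigilance_threshold)
  counts <- aggregate_counts(trials)
  edge <- edge_accuracy_check(counts, threshold = edge_threshold,
                              pooled = pooled_edges)
  edge_by_p <- edge |>
    dplyr::group_by(.data$participant_id) |>
    dplyr::summarise(min_edge_accuracy = min(.data$accuracy),
                     edge_flag = any(.data$accuracy < edge_threshold),
                     .groups = "drop")

  behav <- dplyr::full_join(vig, edge_by_p, by = "participant_id")
  behav_pass <- behav$participant_id[!behav$vigilance_flag & !behav$edge_flag]

  if (is.null(widths)) {
    widths <- cone_widths(
      dplyr::filter(counts, .data$participant_id %in% behav_pass),
      control = control
    )
  }
  fit_by_p <- widths |>
    dplyr::group_by(.data$participant_id) |>
    dplyr::summarise(fit_ok = all(.data$fit_ok), .groups = "drop")

  report <- behav |>
    dplyr::left_join(fit_by_p, by = "participant_id") |>
    dplyr::mutate(
      fit_ok = dplyr::if_else(is.na(.data$fit_ok), NA, .data$fit_ok),
      reasons = purrr::pmap_chr(
        list(.data$vigilance_flag, .data$edge_flag, .data$fit_ok),
        function(v, e, f) {
          r <- c(if (v) "vigilance", if (e) "edge_accuracy",
                 if (!is.na(f) && !f) "fit_failure")
          paste(r, collapse = ",")
        }
      ),
      excluded = .data$reasons != ""
    ) |>
    dplyr::select("participant_id", "vigilance_fail_rate",
                  "min_edge_accuracy", "fit_ok", "excluded", "reasons")

  keep <- report$participant_id[!report$excluded]
  list(
    trials = dplyr::filter(trials, .data$participant_id %in% keep),
    widths = dplyr::filter(widths, .data$participant_id %in% keep),
    report = report
  )
}
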