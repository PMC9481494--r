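#' Cohort specification for the synthetic-observer generator
#'
#' Describes a simulated experiment: how many participants (per ethnicity
#' label), which design, how many trials per design cell, the
#' between-participant spread of cone widths, and any planted contaminant
#' participants for exercising the quality-control rules.
#'
#' Two designs are supported. `"exp1"` crosses the nine-azimuth grid with
#' two visual conditions (direct gaze, eyes closed) at `trials_per_cell`
#' trials each — 180 experimental trials at the default 10 — plus
#' `vigilance_trials` catch trials. `"exp2"` adds an audio-only baseline
#' condition (90 more trials at the default).
#'
#' @param n_participants Named integer vector of participants per ethnicity
#'   label (`white`, `east_asian`), or a single unnamed count (treated as
#'   `white`, matching a single-ethnicity recruitment).
#' @param design `"exp1"` (two conditions) or `"exp2"` (three).
#' @param trials_per_cell Trials per azimuth x condition cell (default 10).
#' @param vigilance_trials Catch trials per participant (default 12, half
#'   auditory, half visual).
#' @param between_participant_sd SD (degrees) of a participant-level shift
#'   added to both boundary magnitudes — a random intercept on cone width.
#' @param contaminant_fraction Fraction of participants simulated as
#'   contaminants, in \[0, 1\].
#' @param contaminant_mode Character vector recycled over contaminant
#'   participants; each of `"random_responder"` (uniform responses),
#'   `"side_biased"` (one side with probability 0.9 everywhere) and
#'   `"vigilance_failer"` (fails each catch trial with probability 0.5)
#'   trips a different exclusion rule.
#' @param honest_vigilance_pass Probability an honest participant passes a
#'   single vigilance trial (default 0.98).
#' @param seed Integer seed making [simulate_cohort()] deterministic.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_participants = c(white = 68, east_asian = 57),
                        design = c("exp1", "exp2"),
                        trials_per_cell = 10,
                        vigilance_trials = 12,
                        between_participant_sd = 3,
                        contaminant_fraction = 0,
                        contaminant_mode = "random_responder",
                        honest_vigilance_pass = 0.98,
                        seed = NULL) {
  design <- match.arg(design)
  if (is.null(names(n_participants))) {
    if (length(n_participants) != 1) {
      abort("unnamed n_participants must be a single count",
            class = "gazecone_parameter_error")
    }
    n_participants <- c(white = unname(n_participants))
  }
  if (!all(names(n_participants) %in% ETHNICITIES)) {
    abort(paste0("ethnicity labels must be among: ",
                 paste(ETHNICITIES, collapse = ", ")),
          class = "gazecone_parameter_error")
  }
  if (contaminant_fraction < 0 || contaminant_fraction > 1) {
    abort("contaminant_fraction must lie in [0, 1]",
          class = "gazecone_parameter_error")
  }
  if (!all(contaminant_mode %in% c("random_responder", "side_biased",
                                   "vigilance_failer"))) {
    abort("unknown contaminant_mode", class = "gazecone_parameter_error")
  }
  structure(
    list(n_participants = n_participants, design = design,
         trials_per_cell = as.integer(trials_per_cell),
         vigilance_trials = as.integer(vigilance_trials),
         between_participant_sd = between_participant_sd,
         contaminant_fraction = contaminant_fraction,
         contaminant_mode = contaminant_mode,
         honest_vigilance_pass = honest_vigilance_pass,
         seed = seed),
    class = "cohort_spec"
  )
}

design_conditions <- function(design) {
  if (design == "exp2") c("baseline", "eyes_closed", "direct_gaze")
  else c("eyes_closed", "direct_gaze")
}

# Draw one participant-condition block of experimental trials.
simulate_block <- function(probs, n_per_azimuth, azimuths) {
  responses <- lapply(seq_along(azimuths), function(i) {
    sample(RESPONSES, n_per_azimuth, replace = TRUE, prob = probs[i, ])
  })
  tibble::tibble(
    azimuth_deg = rep(azimuths, each = n_per_azimuth),
    response = unlist(responses)
  )
}

#' Simulate a cohort of synthetic observers
#'
#' Generates a trial-level dataset with known ground truth from the
#' generative observer model. Honest participants respond according to
#' [category_probabilities()] with a participant-specific boundary shift
#' drawn from `N(0, between_participant_sd)`; the shift is clamped so that
#' at least one degree of boundary separation remains on each side, keeping
#' the middle category well defined. Contaminants respond according to
#' their mode. Trial order is randomized within participant.
#'
#' @param spec A [cohort_spec()].
#' @param base An [observer_params()] object giving the population-level
#'   observer; participant boundaries are shifted around it.
#' @return A list with two tibbles: `trials` (the full trial table, valid
#'   under [validate_trials()]) and `truth` (one row per participant and
#'   condition: true boundaries, true cone width from the crossing oracle,
#'   contaminant status and mode).
#' @export
#' @examples
#' cohort <- simulate_cohort(cohort_spec(n_participants = 4, seed = 42))
#' dplyr::count(cohort$trials, trial_type)
simulate_cohort <- function(spec, base = observer_params()) {
  stopifnot(inherits(spec, "cohort_spec"), inherits(base, "observer_params"))
  if (!is.null(spec$seed)) set.seed(spec$seed)

  n_total <- sum(spec$n_participants)
  ids <- sprintf("P%03d", seq_len(n_total))
  ethnicity <- rep(names(spec$n_participants), spec$n_participants)

  n_cont <- round(spec$contaminant_fraction * n_total)
  cont_idx <- if (n_cont > 0) sort(sample.int(n_total, n_cont)) else integer()
  modes <- rep(NA_character_, n_total)
  if (n_cont > 0) {
    modes[cont_idx] <- rep_len(spec$contaminant_mode, n_cont)
  }

  conditions <- design_conditions(spec$design)
  az <- DESIGN_AZIMUTHS
  half_sep <- (base$boundary_right - base$boundary_left) / 2
  shifts <- pmax(rnorm(n_total, 0, spec$between_participant_sd),
                 -(half_sep - 1))

  trials_list <- vector("list", n_total)
  truth_list <- vector("list", n_total)
  for (i in seq_len(n_total)) {
    mode <- modes[i]
    obs <- base
    obs$boundary_left <- base$boundary_left - shifts[i]
    obs$boundary_right <- base$boundary_right + shifts[i]
    biased_side <- if (!is.na(mode) && mode == "side_biased") {
      sample(c("left", "right"), 1)
    } else {
      NA_character_
    }

    blocks <- lapply(conditions, function(cond) {
      probs <- if (is.na(mode) || mode == "vigilance_failer") {
        pr <- category_probabilities(obs, cond, az)
        as.matrix(pr[, c("p_left", "p_middle", "p_right")])
      } else if (mode == "random_responder") {
        matrix(1 / 3, nrow = length(az), ncol = 3)
      } else {
        p <- c(left = 0.05, middle = 0.05, right = 0.05)
        p[biased_side] <- 0.9
        matrix(p, nrow = length(az), ncol = 3, byrow = TRUE)
      }
      blk <- simulate_block(probs, spec$trials_per_cell, az)
      blk$condition <- cond
      blk
    })
    exp_trials <- dplyr::bind_rows(blocks)
    exp_trials$trial_type <- "experimental"
    exp_trials$vigilance_correct <- NA

    pass_p <- if (!is.na(mode) && mode == "vigilance_failer") 0.5
              else spec$honest_vigilance_pass
    n_vig <- spec$vigilance_trials
    vig <- tibble::tibble(
      azimuth_deg = NA_real_,
      response = NA_character_,
      condition = NA_character_,
      trial_type = rep(c("vigilance_auditory", "vigilance_visual"),
                       length.out = n_vig),
      vigilance_correct = rbinom(n_vig, 1, pass_p) == 1
    )

    ptrials <- dplyr::bind_rows(exp_trials, vig)
    ptrials <- ptrials[sample.int(nrow(ptrials)), , drop = FALSE]
    ptrials$participant_id <- ids[i]
    ptrials$ethnicity <- ethnicity[i]
    trials_list[[i]] <- ptrials

    truth_list[[i]] <- tibble::tibble(
      participant_id = ids[i],
      ethnicity = ethnicity[i],
      condition = conditions,
      boundary_left = obs$boundary_left,
      boundary_right = obs$boundary_right,
      slope = obs$slope,
      lapse_rate = obs$lapse_rate,
      contaminant = !is.na(mode),
      contaminant_mode = mode,
      true_width = if (is.na(mode)) {
        vapply(conditions, function(cond) true_cone_width(obs, cond),
               numeric(1))
      } else {
        NA_real_
      }
    )
  }

  trials <- dplyr::bind_rows(trials_list)
  cols <- c("participant_id", "ethnicity", "condition", "trial_type",
            "azimuth_deg", "response", "vigilance_correct")
  list(trials = trials[, cols], truth = dplyr::bind_rows(truth_list))
}
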