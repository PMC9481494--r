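# Shared fixture builders; everything is generated in code.

# Expected (possibly rounded) response counts for one participant-condition
# block, taken from the joint-logistic model itself.
counts_from_params <- function(mu_left, beta_left, mu_right, beta_right,
                               n_per_cell, azimuths = design_azimuths()) {
  pr <- predict_proportions(
    list(mu_left = mu_left, beta_left = beta_left,
         mu_right = mu_right, beta_right = beta_right),
    azimuths
  )
  tibble::tibble(
    participant_id = "P001", ethnicity = "white", condition = "eyes_closed",
    azimuth_deg = azimuths,
    n_left = round(pr$p_left * n_per_cell),
    n_middle = round(pr$p_middle * n_per_cell),
    n_right = round(pr$p_right * n_per_cell)
  ) |>
    dplyr::mutate(n_total = n_left + n_middle + n_right, complete = TRUE)
}

# A hand-built trial table for one participant: `edge_left_correct` of the
# 10 trials at -40 answered "left" (rest "middle"), and similarly at +40;
# interior azimuths get a clean staircase of responses; `vig_failed` of
# `n_vig` vigilance trials failed.
manual_participant <- function(id, edge_left_correct = 10,
                               edge_right_correct = 10,
                               vig_failed = 0, n_vig = 12,
                               condition = "eyes_closed",
                               ethnicity = "white") {
  az <- design_azimuths()
  resp_for <- function(a) {
    if (a == -40) {
      rep(c("left", "middle"), c(edge_left_correct, 10 - edge_left_correct))
    } else if (a == 40) {
      rep(c("right", "middle"), c(edge_right_correct, 10 - edge_right_correct))
    } else if (a < 0) {
      rep(c("left", "middle"), c(round(10 * (-a) / 40), 10 - round(10 * (-a) / 40)))
    } else if (a > 0) {
      rep(c("right", "middle"), c(round(10 * a / 40), 10 - round(10 * a / 40)))
    } else {
      rep("middle", 10)
    }
  }
  exp_rows <- tibble::tibble(
    participant_id = id, ethnicity = ethnicity, condition = condition,
    trial_type = "experimental",
    azimuth_deg = rep(az, each = 10),
    response = unlist(lapply(az, resp_for)),
    vigilance_correct = NA
  )
  vig_rows <- tibble::tibble(
    participant_id = id, ethnicity = ethnicity, condition = NA_character_,
    trial_type = rep(c("vigilance_auditory", "vigilance_visual"),
                     length.out = n_vig),
    azimuth_deg = NA_real_, response = NA_character_,
    vigilance_correct = rep(c(FALSE, TRUE), c(vig_failed, n_vig - vig_failed))
  )
  dplyr::bind_rows(exp_rows, vig_rows)
}

# Two-condition version of manual_participant with identical clean
# experimental responses in both conditions.
manual_participant_2cond <- function(id, ...) {
  dplyr::bind_rows(
    manual_participant(id, condition = "eyes_closed", ...),
    dplyr::filter(manual_participant(id, condition = "direct_gaze", ...),
                  trial_type == "experimental")
  )
}

# Brute-force crossing oracle: minimise |pL - pM| (or |pR - pM|) on a fine
# grid, independent of the bisection solver.
brute_force_crossings <- function(params, step = 1e-3, range = c(-90, 90)) {
  x <- seq(range[1], range[2], by = step)
  pr <- predict_proportions(params, x)
  dl <- pr$p_left - pr$p_middle
  dr <- pr$p_right - pr$p_middle
  pick <- function(d, direction) {
    s <- sign(d)
    step <- s[-1] - s[-length(s)]
    hits <- if (direction > 0) which(step > 0) else which(step < 0)
    if (length(hits) == 0) return(NA_real_)
    mids <- (x[hits] + x[hits + 1]) / 2
    mids[which.min(abs(mids))]
  }
  c(left = pick(dl, -1), right = pick(dr, 1))
}
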