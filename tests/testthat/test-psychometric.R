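test_that("predicted proportions obey the logistic identities", {
  params <- list(mu_left = -15, beta_left = 0.3, mu_right = 15,
                 beta_right = 0.3)
  # sum to one identically
  pr <- predict_proportions(params, seq(-80, 80, by = 2.5))
  expect_equal(pr$p_left + pr$p_middle + pr$p_right, rep(1, nrow(pr)))
  # logistic midpoint
  expect_equal(predict_proportions(params, -15)$p_left, 0.5)
  expect_equal(predict_proportions(params, 15)$p_right, 0.5)
  # mirror symmetry: (pL,pM,pR)(x) = (pR,pM,pL)(-x)
  x <- seq(-50, 50, by = 10)
  a <- predict_proportions(params, x)
  b <- predict_proportions(params, -x)
  expect_equal(a$p_left, b$p_right)
  expect_equal(a$p_middle, b$p_middle)
})

test_that("predicted proportions match independent hand evaluation", {
  got <- predict_proportions(
    list(mu_left = -15, beta_left = 0.3, mu_right = 15, beta_right = 0.3), 0
  )
  p_left <- 1 / (1 + exp(0.3 * (0 - (-15))))
  p_right <- 1 / (1 + exp(-0.3 * (0 - 15)))
  expect_equal(got$p_left, p_left)
  expect_equal(got$p_right, p_right)
  expect_equal(got$p_middle, 1 - p_left - p_right)
})

test_that("fit_joint recovers generating parameters from near-exact counts", {
  truth <- c(mu_left = -12, beta_left = 0.28, mu_right = 9, beta_right = 0.35)
  counts <- counts_from_params(truth[["mu_left"]], truth[["beta_left"]],
                               truth[["mu_right"]], truth[["beta_right"]],
                               n_per_cell = 1000)
  fit <- fit_joint(counts)
  expect_true(fit$converged)
  expect_lt(abs(fit$params[["mu_left"]] - truth[["mu_left"]]), 0.1)
  expect_lt(abs(fit$params[["mu_right"]] - truth[["mu_right"]]), 0.1)
  expect_lt(abs(fit$params[["beta_left"]] - truth[["beta_left"]]), 0.02)
  expect_lt(abs(fit$params[["beta_right"]] - truth[["beta_right"]]), 0.02)
})

test_that("degenerate all-middle data cannot be fitted", {
  counts <- tibble::tibble(
    participant_id = "P001", ethnicity = "white", condition = "eyes_closed",
    azimuth_deg = design_azimuths(), n_left = 0L, n_middle = 10L,
    n_right = 0L, n_total = 10L, complete = TRUE
  )
  expect_error(fit_joint(counts), class = "gazecone_fit_failure")
  fit <- fit_joint(counts, on_failure = "return")
  expect_false(fit$converged)
  expect_true(length(fit$reasons) > 0)
})

test_that("fewer than four informative azimuths is a data error", {
  counts <- counts_from_params(-10, 0.25, 10, 0.25, 10)[1:3, ]
  expect_error(fit_joint(counts), class = "gazecone_data_error")
})

test_that("mirrored data give mirrored fits", {
  set.seed(5)
  cohort <- simulate_cohort(cohort_spec(n_participants = 1, seed = 55))
  counts <- dplyr::filter(aggregate_counts(cohort$trials),
                          condition == "eyes_closed")
  mirrored <- counts |>
    dplyr::mutate(azimuth_deg = -azimuth_deg,
                  tmp = n_left, n_left = n_right, n_right = tmp) |>
    dplyr::arrange(azimuth_deg)
  f1 <- fit_joint(counts)
  f2 <- fit_joint(mirrored)
  expect_lt(abs(f2$params[["mu_left"]] + f1$params[["mu_right"]]), 0.01)
  expect_lt(abs(f2$params[["mu_right"]] + f1$params[["mu_left"]]), 0.01)
  expect_lt(abs(f2$params[["beta_left"]] - f1$params[["beta_right"]]), 1e-3)
  expect_equal(f1$loss, f2$loss, tolerance = 1e-8)
})

test_that("crossings match the brute-force root oracle", {
  params <- list(mu_left = -15, beta_left = 0.3, mu_right = 15,
                 beta_right = 0.3)
  cr <- find_crossings(params)
  oracle <- brute_force_crossings(params)
  expect_lt(abs(cr$x_left_cross - oracle[["left"]]), 0.005)
  expect_lt(abs(cr$x_right_cross - oracle[["right"]]), 0.005)
  expect_lt(abs(cr$width - (oracle[["right"]] - oracle[["left"]])), 0.01)
  # mirror-symmetric parameters give symmetric crossings
  expect_lt(abs(cr$x_left_cross + cr$x_right_cross), 1e-3)
})

test_that("the step-function limit returns the boundary separation", {
  cr <- find_crossings(list(mu_left = -20, beta_left = 50, mu_right = 20,
                            beta_right = 50))
  expect_lt(abs(cr$width - 40), 0.01)
  expect_equal(cr$status, "ok")
})

test_that("missing crossings are reported in the status", {
  # left curve never meets the middle curve inside the search range
  cr <- find_crossings(list(mu_left = -200, beta_left = 0.3, mu_right = 15,
                            beta_right = 0.3))
  expect_equal(cr$status, "no_left_cross")
  expect_true(is.na(cr$width))
})

test_that("fitted width is invariant to uniform count scaling", {
  counts <- counts_from_params(-11, 0.3, 12, 0.22, 10)
  scaled <- dplyr::mutate(
    counts,
    dplyr::across(c(n_left, n_middle, n_right, n_total), ~ .x * 7L)
  )
  w1 <- fit_joint(counts)$crossings$width
  w2 <- fit_joint(scaled)$crossings$width
  expect_lt(abs(w1 - w2), 1e-4)
})

test_that("cone_widths flags the whole participant when one condition fails", {
  good <- counts_from_params(-10, 0.25, 10, 0.25, 10)
  bad <- good |>
    dplyr::mutate(condition = "direct_gaze", n_left = 0L, n_right = 0L,
                  n_middle = 10L, n_total = 10L)
  res <- cone_widths(dplyr::bind_rows(good, bad))
  expect_equal(nrow(res), 2)
  expect_true(res$fit_ok[res$condition == "eyes_closed"])
  expect_false(res$fit_ok[res$condition == "direct_gaze"])
  expect_true(all(!res$participant_fit_ok))
})

test_that("cone_widths on empty input returns an empty table", {
  empty <- aggregate_counts(manual_participant("P001")[0, ])
  expect_equal(nrow(cone_widths(empty)), 0)
})

test_that("cone widths recover ground truth on honest participants", {
  cohort <- simulate_cohort(
    cohort_spec(n_participants = 8, trials_per_cell = 100,
                between_participant_sd = 2, seed = 61)
  )
  w <- cone_widths(aggregate_counts(cohort$trials))
  expect_true(all(w$fit_ok))
  joined <- dplyr::inner_join(
    w, cohort$truth[, c("participant_id", "condition", "true_width")],
    by = c("participant_id", "condition")
  )
  expect_lt(mean(abs(joined$width - joined$true_width)), 1)
  expect_gt(stats::cor(joined$width, joined$true_width), 0.9)
})
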