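test_that("vigilance flag uses a strict 20% threshold", {
  trials <- dplyr::bind_rows(
    manual_participant("P001", vig_failed = 2),   # 2/12 ~ 0.167
    manual_participant("P002", vig_failed = 3),   # 3/12 = 0.25
    manual_participant("P003", vig_failed = 0)
  )
  vc <- vigilance_check(trials)
  expect_equal(vc$vigilance_fail_rate[vc$participant_id == "P001"], 1 / 6)
  expect_false(vc$vigilance_flag[vc$participant_id == "P001"])
  expect_true(vc$vigilance_flag[vc$participant_id == "P002"])
  expect_false(vc$vigilance_flag[vc$participant_id == "P003"])
})

test_that("a participant without vigilance trials is a data error", {
  trials <- dplyr::filter(manual_participant("P001"),
                          trial_type == "experimental")
  expect_error(vigilance_check(trials), class = "gazecone_data_error")
})

test_that("edge accuracy flags strictly below 80% and treats middle as wrong", {
  trials <- dplyr::bind_rows(
    manual_participant("P001", edge_left_correct = 8, edge_right_correct = 10),
    manual_participant("P002", edge_left_correct = 10, edge_right_correct = 7)
  )
  ec <- edge_accuracy_check(aggregate_counts(trials))
  p1 <- dplyr::filter(ec, participant_id == "P001")
  expect_equal(min(p1$accuracy), 0.8)
  expect_false(any(p1$edge_flag))          # exactly 80% is retained
  p2 <- dplyr::filter(ec, participant_id == "P002")
  expect_equal(min(p2$accuracy), 0.7)
  expect_true(all(p2$edge_flag))
})

test_that("missing edge azimuths are a data error", {
  trials <- dplyr::filter(manual_participant("P001"), azimuth_deg != 40 |
                            trial_type != "experimental")
  expect_error(edge_accuracy_check(aggregate_counts(trials)),
               class = "gazecone_data_error")
})

test_that("a side-biased responder is flagged through the opposite edge", {
  cohort <- simulate_cohort(
    cohort_spec(n_participants = 4, contaminant_fraction = 0.25,
                contaminant_mode = "side_biased", seed = 17)
  )
  ec <- edge_accuracy_check(aggregate_counts(cohort$trials))
  biased <- unique(cohort$truth$participant_id[cohort$truth$contaminant])
  expect_true(all(ec$edge_flag[ec$participant_id == biased]))
  # expected accuracy at the disfavoured edge is ~0.05
  expect_lt(min(ec$accuracy[ec$participant_id == biased]), 0.2)
})

test_that("planted contaminants are excluded with their matching reason", {
  cohort <- simulate_cohort(
    cohort_spec(n_participants = 13, contaminant_fraction = 3 / 13,
                contaminant_mode = c("random_responder", "side_biased",
                                     "vigilance_failer"),
                seed = 29)
  )
  res <- apply_exclusions(cohort$trials)
  truth <- dplyr::distinct(cohort$truth, participant_id, contaminant,
                           contaminant_mode)
  expect_setequal(res$report$participant_id[res$report$excluded],
                  truth$participant_id[truth$contaminant])
  reason_of <- setNames(res$report$reasons, res$report$participant_id)
  mode_of <- setNames(truth$contaminant_mode, truth$participant_id)
  for (p in truth$participant_id[truth$contaminant]) {
    expected <- switch(mode_of[[p]],
                       random_responder = "edge_accuracy",
                       side_biased = "edge_accuracy",
                       vigilance_failer = "vigilance")
    expect_equal(reason_of[[p]], expected)
  }
  expect_false(any(res$trials$participant_id %in%
                     truth$participant_id[truth$contaminant]))
})

test_that("a clean cohort has zero exclusions", {
  cohort <- simulate_cohort(cohort_spec(n_participants = 5, seed = 37))
  res <- apply_exclusions(cohort$trials)
  expect_false(any(res$report$excluded))
  expect_equal(nrow(res$trials), nrow(cohort$trials))
})

test_that("boundary cases sit on the retained side of both thresholds", {
  trials <- manual_participant("P001", vig_failed = 2, n_vig = 10,
                               edge_left_correct = 8, edge_right_correct = 8)
  trials <- dplyr::bind_rows(
    trials,
    dplyr::filter(manual_participant("P001", condition = "direct_gaze"),
                  trial_type == "experimental")
  )
  res <- apply_exclusions(trials)
  expect_false(res$report$excluded)
  expect_equal(res$report$vigilance_fail_rate, 0.2)
  expect_equal(res$report$min_edge_accuracy, 0.8)
})

test_that("a participant tripping two rules gets both reasons", {
  trials <- manual_participant_2cond("P001", vig_failed = 6,
                                     edge_left_correct = 3)
  res <- apply_exclusions(trials)
  expect_true(res$report$excluded)
  expect_setequal(strsplit(res$report$reasons, ",")[[1]],
                  c("vigilance", "edge_accuracy"))
})

test_that("exclusion is monotone in failed vigilance trials", {
  base <- manual_participant_2cond("P001", vig_failed = 4)
  res1 <- apply_exclusions(base)
  expect_true(res1$report$excluded)
  more <- manual_participant_2cond("P001", vig_failed = 7)
  res2 <- apply_exclusions(more)
  expect_true(res2$report$excluded)
})

test_that("the retained set does not depend on participant order", {
  cohort <- simulate_cohort(
    cohort_spec(n_participants = 6, contaminant_fraction = 1 / 3,
                contaminant_mode = "side_biased", seed = 43)
  )
  res_a <- apply_exclusions(cohort$trials)
  reversed <- dplyr::arrange(cohort$trials, dplyr::desc(participant_id))
  res_b <- apply_exclusions(reversed)
  expect_setequal(unique(res_a$trials$participant_id),
                  unique(res_b$trials$participant_id))
})

test_that("a failed fit in any condition excludes the participant wholesale", {
  trials <- dplyr::bind_rows(manual_participant_2cond("P001"),
                             manual_participant_2cond("P002"))
  widths <- cone_widths(aggregate_counts(trials))
  # mark one of P002's conditions as unfittable
  widths$fit_ok[widths$participant_id == "P002" &
                  widths$condition == "direct_gaze"] <- FALSE
  res <- apply_exclusions(trials, widths = widths)
  p2 <- dplyr::filter(res$report, participant_id == "P002")
  expect_true(p2$excluded)
  expect_equal(p2$reasons, "fit_failure")
  expect_false("P002" %in% res$trials$participant_id)
  expect_false("P002" %in% res$widths$participant_id)
  expect_false(dplyr::filter(res$report, participant_id == "P001")$excluded)
})
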