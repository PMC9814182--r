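test_that("cumulative means follow the inclusive running-mean definition", {
  expect_equal(cumulative_mean(c(3, 3, 3), 3), 3)
  expect_equal(cumulative_mean(c(1, 2, 3), 2), 1.5)
  expect_equal(cumulative_mean(c(1, 2, 3), 3), 2)
  # missing days drop out of both numerator and denominator
  expect_equal(cumulative_mean(c(2, NA, 4), 3), 3)
  # carried forward over a missing day
  expect_equal(cumulative_mean(c(2, NA, 4), 2), 2)
  # no completed survey yet -> absent
  expect_true(is.na(cumulative_mean(c(NA, 2), 1)))
})

test_that("deviation is the day response minus the inclusive mean", {
  expect_equal(deviation_score(3, cumulative_mean(c(1, 2, 3), 3)), 1)
  # first observed day: mean includes the day itself, so deviation is 0
  v <- c(5, 2, 4)
  expect_equal(deviation_score(v[1], cumulative_mean(v, 1)), 0)
  expect_true(is.na(deviation_score(NA, 2)))
  # constant series deviates by 0 everywhere
  cv <- rep(4, 6)
  expect_equal(deviation_score(cv, cumulative_mean(cv)), rep(0, 6))
})

test_that("outcome binarisation maps 0 to 0 and any frequency to 1", {
  expect_equal(binarize_ideation(c(0, 1, 2, 3, 4, NA)),
               c(0L, 1L, 1L, 1L, 1L, NA_integer_))
  expect_error(binarize_ideation(5))
})

test_that("feature rows enumerate (participant, outcome day) pairs", {
  feats <- build_features(tiny_records(days = 3), "simple_with_duration")
  # outcome days 2 and 3 for each of two participants
  expect_equal(nrow(feats), 4)
  expect_equal(sort(unique(feats$outcome_day)), c(2L, 3L))
  expect_equal(feature_predictors(feats), variant_predictors("simple_with_duration"))
})

test_that("predictor counts are 13/23/12/21 across the four variants", {
  expect_length(variant_predictors("simple_with_duration"), 13)
  expect_length(variant_predictors("complex_with_duration"), 23)
  expect_length(variant_predictors("simple_without_duration"), 12)
  expect_length(variant_predictors("complex_without_duration"), 21)
  expect_false(any(grepl("ideation_duration",
                         variant_predictors("complex_without_duration"))))
})

test_that("participants without two consecutive completed surveys drop out", {
  rec <- tiny_records(days = 3)
  # participant B completes only days 1 and 3
  rec <- rec[!(rec$participant_id == "B" & rec$day_index == 2), ]
  rec <- complete_daily_records(rec[setdiff(names(rec), "completed")],
                                study_length = 3)
  feats <- build_features(rec, "simple_with_duration")
  expect_equal(unique(feats$participant_id), "A")

  only_day1 <- rec[rec$participant_id == "A" & rec$day_index == 1, ]
  rec2 <- complete_daily_records(
    only_day1[setdiff(names(only_day1), "completed")], study_length = 3)
  expect_error(build_features(rec2, "simple_with_duration"),
               "two consecutive")
})

test_that("a missed previous day keeps the row with carried-forward mean", {
  rec <- tiny_records(days = 4)
  # participant A misses day 3; day-4 outcome row must survive
  rec <- rec[!(rec$participant_id == "A" & rec$day_index == 3), ]
  rec <- complete_daily_records(rec[setdiff(names(rec), "completed")],
                                study_length = 4)
  feats <- build_features(rec, "complex_with_duration")
  row4 <- feats[feats$participant_id == "A" & feats$outcome_day == 4, ]
  expect_equal(row4$prev_day_missing, 1L)
  expect_true(is.na(row4$hopelessness_cs))
  a <- rec[rec$participant_id == "A", ]
  expect_equal(row4$hopelessness_cm,
               mean(a$hopelessness[c(1, 2)]))  # days 1-2 only
  # rows with a missed outcome day are excluded
  expect_false(any(feats$participant_id == "A" & feats$outcome_day == 3))
})

test_that("study week and day of week derive from the outcome day", {
  feats <- build_features(sim_default()$records, "simple_with_duration")
  expect_equal(feats$study_week, pmin(ceiling(feats$outcome_day / 7), 4))
  expect_equal(as.character(feats$day_of_week),
               as.character(day_of_week_factor(feats$outcome_day)))
})

test_that("predictors never use information beyond the predictor day", {
  sim <- sim_default()
  full <- build_features(sim$records, "complex_with_duration")
  t_cut <- 14L
  truncated <- sim$records[sim$records$day_index <= t_cut, ]
  part <- build_features(truncated, "complex_with_duration")
  shared <- dplyr::semi_join(
    full, part[c("participant_id", "outcome_day")],
    by = c("participant_id", "outcome_day"))
  expect_equal(as.data.frame(shared), as.data.frame(part),
               tolerance = 1e-12)
})
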