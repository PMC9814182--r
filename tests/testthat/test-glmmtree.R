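test_that("a single strong split is recovered with its threshold", {
  # one-split ground truth with no participant heterogeneity; the
  # generator is the oracle for the fitted structure
  truth <- tree_split("burdensomeness_cm", 4,
                      left = tree_leaf(-1.2), right = tree_leaf(1.2))
  cfg <- sim_config(n_participants = 100, random_intercept_sd = 0,
                    truth_tree = truth, calibration_constant = -0.2,
                    rng_seed = 1)
  hits <- 0
  for (s in 1:8) {
    cfg$rng_seed <- 1000L + s
    sim <- simulate_study(cfg)
    feats <- build_features(sim$records, "complex_with_duration")
    fit <- suppressWarnings(glmm_tree(feats, config = study_config()))
    root <- fit$tree
    if (!root$is_leaf && root$variable == "burdensomeness_cm" &&
        abs(root$threshold - 4) <= 0.3) {
      hits <- hits + 1
    }
  }
  expect_gte(hits, 7)
})

test_that("pure noise rarely splits the root", {
  cfg <- null_config()
  splits <- 0
  for (s in 1:6) {
    cfg$rng_seed <- 2000L + s
    sim <- simulate_study(cfg)
    feats <- build_features(sim$records, "complex_with_duration")
    fit <- suppressWarnings(glmm_tree(feats, config = study_config()))
    splits <- splits + (fit$n_leaves > 1)
  }
  expect_lte(splits, 1)
})

test_that("leaf probabilities use the smoothed empirical rate", {
  feats <- features_complex()
  # single-class outcome degenerates to a smoothed root leaf with warning
  sub <- feats[feats$outcome == 1, ][1:60, ]
  expect_warning(fit <- glmm_tree(sub, config = study_config()),
                 "single class")
  expect_equal(fit$n_leaves, 1L)
  expect_equal(fit$tree$probability, (60 + 0.5) / (60 + 1))

  # root-only model predicts the overall smoothed rate everywhere
  f0 <- features_null()
  fit0 <- root_only_fit()
  expect_equal(fit0$n_leaves, 1L)
  k <- sum(f0$outcome)
  expect_equal(unique(predict(fit0, f0)),
               (k + 0.5) / (nrow(f0) + 1))
})

test_that("prediction honours random effects only for known participants", {
  fit <- fitted_small_tree()
  feats <- build_features(simulate_study(recovery_config(907L))$records,
                          "complex_with_duration")
  row <- feats[1, ]
  p_pop <- predict(fit, row)
  pid <- as.character(row$participant_id)
  b <- fit$ranef[[pid]]
  p_re <- predict(fit, row, use_random_effects = TRUE)
  expect_equal(qlogis(p_re) - qlogis(p_pop), b, tolerance = 1e-10)

  unseen <- row
  unseen$participant_id <- "ZZZ"
  expect_equal(predict(fit, unseen, use_random_effects = TRUE), p_pop)
  # unknown predictor columns are refused
  expect_error(predict(fit, row[, 1:3]), "lacks predictor")
})

test_that("row order does not change the fitted tree", {
  feats <- features_complex()
  fit1 <- suppressWarnings(glmm_tree(feats, config = study_config()))
  set.seed(5)
  shuffled <- feats[sample(nrow(feats)), ]
  attr(shuffled, "predictors") <- attr(feats, "predictors")
  fit2 <- suppressWarnings(glmm_tree(shuffled, config = study_config()))
  expect_equal(tidy(fit1)$rule, tidy(fit2)$rule)
  expect_equal(tidy(fit1)$probability, tidy(fit2)$probability)
  expect_equal(fit1$sigma_b, fit2$sigma_b, tolerance = 1e-6)
})

test_that("the alternation log-likelihood stabilises", {
  # the trace may dip while the tree structure is still changing (a
  # simpler tree has fewer leaf parameters), but it must settle: once
  # the structure is stable the mixed-model refit is deterministic
  fit <- fitted_small_tree()
  expect_gte(length(fit$fit_log), 1)
  expect_true(all(is.finite(fit$fit_log)))
  if (length(fit$fit_log) > 1) {
    expect_lt(abs(diff(utils::tail(fit$fit_log, 2))), 1e-4)
  }
  expect_true(fit$converged)
})

test_that("with sigma_b near zero the tree matches an offset-free fit", {
  truth <- tree_split("burdensomeness_cm", 4,
                      left = tree_leaf(-1.2), right = tree_leaf(1.2))
  cfg <- sim_config(n_participants = 120, random_intercept_sd = 0,
                    truth_tree = truth, calibration_constant = -0.2,
                    rng_seed = 5150)
  feats <- build_features(simulate_study(cfg)$records,
                          "complex_with_duration")
  full <- suppressWarnings(glmm_tree(feats, config = study_config()))
  plain <- suppressWarnings(glmm_tree(feats, config = study_config(),
                                      max_iter = 1))
  expect_lt(full$sigma_b, 0.25)
  expect_equal(tidy(full)$rule, tidy(plain)$rule)
})
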