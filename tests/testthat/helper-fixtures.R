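# Shared fixtures, built in code and cached for the duration of the test
# run so repeated tests do not re-pay simulation or calibration costs.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# A tiny fully-completed two-participant study, values chosen by hand so
# feature arithmetic can be verified against direct sums.
tiny_records <- function(days = 3) {
  base <- tidyr::expand_grid(
    participant_id = c("A", "B"),
    day_index = seq_len(days)
  )
  for (it in item_schema()$item) {
    rng <- item_schema()[item_schema()$item == it, ]
    base[[it]] <- rep(seq(rng$min, rng$max,
                          length.out = days)[seq_len(days)], 2)
    base[[it]] <- round(base[[it]])
  }
  base$ideation_frequency <- rep(rep_len(c(0, 1, 2), days), 2)
  base$ideation_duration <- ifelse(base$ideation_frequency == 0, 0, 2)
  base$completed <- TRUE
  base
}

# Default-condition simulated study (78 x 28, calibrated once).
sim_default <- function() {
  cached("sim_default", {
    cfg <- sim_config(rng_seed = 424L)
    cfg$calibration_constant <- cached("const_default",
                                       calibrate_constant(cfg))
    simulate_study(cfg)
  })
}

features_complex <- function() {
  cached("features_complex",
         build_features(sim_default()$records, "complex_with_duration"))
}

# Calibration constant for the null (flat-tree, no random intercept)
# generator, shared across type-I replicates.
null_config <- function(n_participants = 100, seed = 1L) {
  cfg <- sim_config(n_participants = n_participants,
                    random_intercept_sd = 0,
                    truth_tree = flat_truth_tree(), rng_seed = seed)
  cfg$calibration_constant <- cached("const_null", calibrate_constant(cfg))
  cfg
}

# Recovery-condition generator: the default two-split truth tree with
# sigma_b = 1 (also the default), 200 participants.
recovery_config <- function(seed = 1L) {
  cfg <- sim_config(n_participants = 200, rng_seed = seed)
  cfg$calibration_constant <- cached("const_recovery",
                                     calibrate_constant(cfg))
  cfg
}

# Random rows over a fitted tree's predictor space, including missing
# values, for routing/rule agreement checks.
random_probe_rows <- function(fit, n) {
  lv <- levels(day_of_week_factor(1))
  cols <- purrr::imap(fit$predictor_classes, function(cl, v) {
    if (cl %in% c("factor", "character")) {
      factor(sample(lv, n, replace = TRUE), levels = lv)
    } else {
      x <- runif(n, -3, 8)
      x[runif(n) < 0.1] <- NA
      x
    }
  })
  tibble::as_tibble(cols)
}

cv_complex_2rep <- function() {
  cached("cv_complex_2rep", suppressWarnings(
    run_cv(features_complex(),
           config = study_config(n_repetitions = 2, rng_seed = 10))))
}

# Null-data features (no signal, no heterogeneity) and the root-only fit
# they induce.
features_null <- function() {
  cached("features_null", {
    cfg <- null_config()
    cfg$rng_seed <- 77L
    build_features(simulate_study(cfg)$records, "complex_with_duration")
  })
}

root_only_fit <- function() {
  cached("root_only_fit", suppressWarnings(
    glmm_tree(features_null(), config = study_config(alpha = 1e-12))))
}

# A small fitted tree on strong-signal data, reused by rule/prediction
# agreement tests.
fitted_small_tree <- function() {
  cached("fitted_small_tree", {
    cfg <- recovery_config(seed = 907L)
    sim <- simulate_study(cfg)
    feats <- build_features(sim$records, "complex_with_duration")
    suppressWarnings(glmm_tree(feats, config = study_config()))
  })
}
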