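# Participant-blocked, stratified, repeated k-fold cross-validation.
# Participants serve as blocks (all of a participant's rows share a fold)
# and folds are balanced on a median split of each participant's observed
# ideation rate, so outcome prevalence stays comparable across folds.

#' Median-split risk strata
#'
#' Labels each participant `high` if their proportion of observed outcome
#' days with ideation endorsed exceeds the across-participant median, and
#' `low` otherwise (ties at the median are low).
#'
#' @param features Feature table from [build_features()].
#' @return Tibble with `participant_id`, `proportion`, `stratum`.
#' @export
stratify_participants <- function(features) {
  props <- features |>
    dplyr::summarise(proportion = mean(.data$outcome),
                     .by = "participant_id")
  if (nrow(props) < 2) stop("need at least 2 participants", call. = FALSE)
  med <- median(props$proportion)
  props$stratum <- ifelse(props$proportion > med, "high", "low")
  dplyr::arrange(props, .data$participant_id)
}

#' Build one participant-to-fold assignment
#'
#' Within each stratum, participants are shuffled with the seeded RNG and
#' dealt round-robin into `k` folds, so per-fold stratum counts differ
#' from perfect balance by at most one.
#'
#' @param strata Output of [stratify_participants()].
#' @param k Number of folds.
#' @param seed Integer seed; the same seed reproduces the same plan.
#' @return Tibble with `participant_id`, `stratum`, `fold` (1..k).
#' @export
make_fold_plan <- function(strata, k, seed) {
  counts <- table(strata$stratum)
  if (k > min(counts)) {
    stop("k = ", k, " exceeds the size of the smaller stratum (",
         min(counts), ")", call. = FALSE)
  }
  set.seed(seed)
  plan <- strata |>
    dplyr::select("participant_id", "stratum") |>
    dplyr::group_by(.data$stratum) |>
    dplyr::group_modify(function(g, key) {
      g <- g[sample.int(nrow(g)), , drop = FALSE]
      g$fold <- rep_len(seq_len(k), nrow(g))
      g
    }) |>
    dplyr::ungroup()
  dplyr::arrange(plan, .data$participant_id)
}

#' Repeated blocked stratified cross-validation of a GLMM tree
#'
#' For each repetition `r` (seed = `config$rng_seed + r`) a fresh fold plan
#' is drawn; for each fold, a GLMM tree is fitted on the training
#' participants and the held-out participants' rows are scored without
#' random effects (test participants are unseen, so `b = 0`).
#' Out-of-fold predictions are pooled within each repetition and summarised
#' with AUC, the closest-top-left cutoff, sensitivity, specificity and
#' PPV; aggregates are the across-repetition mean and standard error
#' (`sd / sqrt(R)`, `NA` when `R = 1`).
#'
#' @param features Feature table from [build_features()].
#' @param predictors Predictor columns; defaults to the table's attribute.
#' @param config A [study_config()].
#' @return An object of class `cv_result`: `predictions` (pooled
#'   out-of-fold scores per repetition), `per_repetition` metrics, and
#'   `summary` (mean and s.e. per metric).
#' @export
run_cv <- function(features, predictors = NULL, config = study_config()) {
  predictors <- predictors %||% feature_predictors(features)
  strata <- stratify_participants(features)
  reps <- seq_len(config$n_repetitions)
  all_pred <- vector("list", length(reps))
  per_rep <- vector("list", length(reps))
  for (r in reps) {
    plan <- make_fold_plan(strata, config$k_folds,
                           seed = config$rng_seed + r)
    fold_of <- setNames(plan$fold, plan$participant_id)
    row_fold <- unname(fold_of[as.character(features$participant_id)])
    scores <- rep(NA_real_, nrow(features))
    for (f in seq_len(config$k_folds)) {
      test <- row_fold == f
      train <- features[!test, , drop = FALSE]
      if (length(unique(train$outcome)) < 2) {
        warning("training outcome single-class in fold ", f,
                "; using a degenerate root model", call. = FALSE)
      }
      fit <- suppressWarnings(
        glmm_tree(train, predictors = predictors, config = config)
      )
      scores[test] <- predict(fit, features[test, , drop = FALSE],
                              use_random_effects = FALSE)
    }
    stopifnot(!anyNA(scores))
    all_pred[[r]] <- tibble::tibble(
      repetition = r,
      participant_id = features$participant_id,
      outcome_day = features$outcome_day,
      fold = row_fold,
      outcome = features$outcome,
      score = scores
    )
    per_rep[[r]] <- dplyr::bind_cols(
      tibble::tibble(repetition = r),
      score_predictions(scores, features$outcome)
    )
  }
  per_rep <- dplyr::bind_rows(per_rep)
  metrics <- c("auc", "ppv", "sensitivity", "specificity")
  summary <- tidyr::pivot_longer(per_rep[c("repetition", metrics)],
                                 -"repetition",
                                 names_to = "metric") |>
    dplyr::summarise(
      mean = mean(.data$value),
      se = if (dplyr::n() > 1) sd(.data$value) / sqrt(dplyr::n())
           else NA_real_,
      .by = "metric"
    )
  structure(
    list(predictions = dplyr::bind_rows(all_pred),
         per_repetition = per_rep, summary = summary,
         k_folds = config$k_folds, n_repetitions = config$n_repetitions),
    class = "cv_result")
}

#' Cross-validate the four model variants
#'
#' Builds the feature table for each requested variant and runs
#' [run_cv()], returning one summary table shaped like a published
#' performance-metrics table (mean and s.e. per metric per variant).
#'
#' @param records Daily record tibble.
#' @param config A [study_config()].
#' @param variants Variants to evaluate (default all four).
#' @return Tibble with `variant`, `metric`, `mean`, `se`.
#' @export
cv_variants <- function(records, config = study_config(),
                        variants = model_variants()) {
  purrr::map(variants, function(v) {
    feats <- build_features(records, variant = v)
    res <- run_cv(feats, config = config)
    dplyr::mutate(res$summary, variant = v, .before = 1)
  }) |>
    dplyr::bind_rows()
}

#' @export
print.cv_result <- function(x, ...) {
  cat("Blocked stratified cross-validation:",
      x$k_folds, "folds x", x$n_repetitions, "repetitions\n")
  print(x$summary)
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.cv_result <- function(x, ...) {
  x$per_repetition
}

#' @exportS3Method generics::glance
glance.cv_result <- function(x, ...) {
  wide <- tidyr::pivot_wider(x$summary, names_from = "metric",
                             values_from = c("mean", "se"),
                             names_glue = "{metric}_{.value}")
  dplyr::mutate(wide, k_folds = x$k_folds,
                n_repetitions = x$n_repetitions)
}

#' @exportS3Method ggplot2::autoplot
autoplot.cv_result <- function(object, ...) {
  ggplot2::ggplot(object$per_repetition |>
                    tidyr::pivot_longer(c("auc", "ppv", "sensitivity",
                                          "specificity"),
                                        names_to = "metric"),
                  ggplot2::aes(x = .data$metric, y = .data$value)) +
    ggplot2::geom_boxplot(outlier.shape = NA, fill = "grey90") +
    ggplot2::geom_jitter(width = 0.1, alpha = 0.6, size = 1) +
    ggplot2::labs(x = NULL, y = "Cross-validated value",
                  title = "Out-of-fold performance across repetitions") +
    ggplot2::theme_minimal()
}
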