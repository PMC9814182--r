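#' Cumulative person-specific mean
#'
#' For one participant and one item, the running mean of responses on
#' completed survey days up to and including day `t`: the within-person sum
#' of present responses on days `1..t` divided by the number of completed
#' surveys on days `1..t`. Days without a completed survey contribute
#' nothing; if no survey has been completed by day `t` the mean is `NA`.
#'
#' @param values Numeric vector of day-indexed responses (position `i` =
#'   day `i`), with `NA` on missing days.
#' @param t Day index (scalar) or vector of day indices; defaults to all
#'   days, giving the full running-mean series.
#' @return Numeric vector of cumulative means at the requested day(s).
#' @export
#' @examples
#' cumulative_mean(c(1, 2, 3), 2)        # 1.5
#' cumulative_mean(c(2, NA, 4), 3)       # 3: two completed surveys
cumulative_mean <- function(values, t = seq_along(values)) {
  stopifnot(all(t >= 1), all(t <= length(values)))
  present <- !is.na(values)
  csum <- cumsum(ifelse(present, values, 0))
  cn <- cumsum(present)
  out <- ifelse(cn[t] > 0, csum[t] / cn[t], NA_real_)
  out
}

#' Deviation from the cumulative person-specific mean
#'
#' The day-`t` change score: the day-`t` response minus the cumulative mean
#' through day `t` (inclusive). On a participant's first completed day the
#' deviation is identically 0, because the mean already includes that day.
#' `NA` if either input is absent.
#'
#' @param value Day-`t` response.
#' @param cum_mean Cumulative mean through day `t`.
#' @return `value - cum_mean`.
#' @export
deviation_score <- function(value, cum_mean) {
  value - cum_mean
}

#' Binarise ideation frequency
#'
#' Maps the 0-4 ideation-frequency response to the presence/absence
#' outcome: 0 stays 0, any positive frequency becomes 1; `NA` is preserved
#' (rows with an unobserved outcome day are excluded downstream).
#'
#' @param frequency Integer vector in 0..4 (or `NA`).
#' @return Integer 0/1/`NA` vector.
#' @export
binarize_ideation <- function(frequency) {
  stopifnot(all(is.na(frequency) | (frequency >= 0 & frequency <= 4)))
  ifelse(is.na(frequency), NA_integer_, as.integer(frequency > 0))
}

#' Model variants
#'
#' Four predictor sets are supported. "Simple" variants use the previous
#' day's raw response per item; "complex" variants use, per item, the
#' cumulative person-specific mean (`_cm`) and the deviation from that mean
#' (`_cs`). The `without_duration` variants drop all ideation-duration
#' predictors. Every variant additionally carries `study_week`,
#' `day_of_week`, and `prev_day_missing`.
#'
#' @return Character vector of variant names.
#' @export
model_variants <- function() {
  c("simple_with_duration", "complex_with_duration",
    "simple_without_duration", "complex_without_duration")
}

context_predictors <- function() {
  c("study_week", "day_of_week", "prev_day_missing")
}

#' Predictor names for a model variant
#'
#' @param variant One of [model_variants()].
#' @return Character vector: 13 predictors for simple-with-duration, 23 for
#'   complex-with-duration, 12 and 21 for the without-duration variants.
#' @export
variant_predictors <- function(variant = model_variants()) {
  variant <- match.arg(variant)
  items <- predictor_items()
  if (grepl("without_duration", variant)) {
    items <- setdiff(items, "ideation_duration")
  }
  base <- if (grepl("^simple", variant)) {
    paste0(items, "_prev")
  } else {
    c(paste0(items, "_cm"), paste0(items, "_cs"))
  }
  c(base, context_predictors())
}

#' Keep participants with at least two consecutive completed surveys
#'
#' The analytic inclusion rule: a participant contributes only if they
#' completed surveys on at least one pair of adjacent days (otherwise no
#' lagged prediction row with an observed previous day exists).
#'
#' @param records Daily record tibble.
#' @return Filtered tibble.
#' @export
filter_eligible_participants <- function(records) {
  elig <- records |>
    dplyr::arrange(.data$participant_id, .data$day_index) |>
    dplyr::summarise(
      ok = any(.data$completed & dplyr::lag(.data$completed, default = FALSE)),
      .by = "participant_id"
    )
  keep <- elig$participant_id[elig$ok]
  dplyr::filter(records, .data$participant_id %in% keep)
}

#' Build the lagged feature table for one model variant
#'
#' One row per (participant, outcome day) pair where the outcome-day survey
#' was completed and `outcome_day >= 2`. Predictors use only information
#' from days `1..t` with `t = outcome_day - 1`:
#' * `<item>_prev` — the day-`t` response (`NA` if day `t` was missed);
#' * `<item>_cm` — cumulative person-specific mean through day `t`
#'   (carried forward over missed days);
#' * `<item>_cs` — day-`t` deviation from that mean (`NA` if day `t`
#'   missed);
#' * `prev_day_missing` — 1 if the day-`t` survey was missed;
#' * `study_week` — `ceiling(outcome_day / 7)` clipped to 4;
#' * `day_of_week` — Mon..Sun factor with day 1 = Mon by convention.
#'
#' Rows with a missed previous day are retained (the tree learner routes
#' missing values along the majority branch); rows with an unobserved
#' outcome are excluded because the outcome cannot be scored. Participants
#' without two consecutive completed surveys are excluded entirely.
#'
#' @param records Daily record tibble (see [read_daily_csv()]).
#' @param variant One of [model_variants()].
#' @return A tibble with identifier columns (`participant_id`,
#'   `outcome_day`), the binary `outcome`, and the variant's predictors.
#'   The predictor names are attached as the `"predictors"` attribute.
#' @export
build_features <- function(records, variant = model_variants()) {
  variant <- match.arg(variant)
  if (nrow(records) == 0) stop("no daily records supplied", call. = FALSE)
  records <- filter_eligible_participants(records)
  if (nrow(records) == 0) {
    stop("no participant has two consecutive completed surveys",
         call. = FALSE)
  }
  items <- predictor_items()
  long <- records |>
    dplyr::arrange(.data$participant_id, .data$day_index) |>
    dplyr::mutate(
      dplyr::across(dplyr::all_of(items),
                    list(cm = ~ cumulative_mean(.x)),
                    .names = "{.col}_cm"),
      .by = "participant_id"
    )
  for (it in items) {
    long[[paste0(it, "_cs")]] <-
      deviation_score(long[[it]], long[[paste0(it, "_cm")]])
  }
  # day-t predictor block joined to the day-(t+1) outcome
  pred <- long |>
    dplyr::select("participant_id", "day_index", "completed",
                  dplyr::all_of(c(items,
                                  paste0(items, "_cm"),
                                  paste0(items, "_cs")))) |>
    dplyr::rename_with(~ paste0(.x, "_prev"), dplyr::all_of(items)) |>
    dplyr::mutate(outcome_day = .data$day_index + 1L,
                  prev_day_missing = as.integer(!.data$completed)) |>
    dplyr::select(-"completed", -"day_index")
  outc <- long |>
    dplyr::filter(.data$completed, .data$day_index >= 2L) |>
    dplyr::transmute(
      participant_id = .data$participant_id,
      outcome_day = .data$day_index,
      outcome = binarize_ideation(.data$ideation_frequency)
    )
  tab <- dplyr::inner_join(outc, pred,
                           by = c("participant_id", "outcome_day")) |>
    dplyr::mutate(
      study_week = pmin(ceiling(.data$outcome_day / 7), 4),
      day_of_week = day_of_week_factor(.data$outcome_day)
    ) |>
    dplyr::arrange(.data$participant_id, .data$outcome_day)
  preds <- variant_predictors(variant)
  out <- tab[c("participant_id", "outcome_day", "outcome", preds)]
  attr(out, "predictors") <- preds
  attr(out, "variant") <- variant
  out
}

#' Map a day index to a day-of-week factor
#'
#' Day 1 (first post-discharge day) is Monday by convention; real calendar
#' alignment is unknown for simulated data.
#'
#' @param day_index Integer vector of day indices (1-based).
#' @return Factor with levels Mon..Sun.
#' @export
day_of_week_factor <- function(day_index) {
  lv <- c("Mon", "Tue", "Wed", "Thu", "Fri", "Sat", "Sun")
  factor(lv[((day_index - 1L) %% 7L) + 1L], levels = lv)
}

#' Write a feature table to CSV
#'
#' Column order is stable: identifiers, outcome, then the variant's
#' predictors in declared order.
#'
#' @param features Table from [build_features()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_features_csv <- function(features, path) {
  readr::write_csv(features, path, progress = FALSE)
  invisible(path)
}

#' Read a feature table written by [write_features_csv()]
#'
#' @param path CSV path.
#' @param variant The model variant the table was built for (restores the
#'   predictor list and the day-of-week factor levels).
#' @return Feature tibble with the `"predictors"` attribute restored.
#' @export
read_features_csv <- function(path, variant = model_variants()) {
  variant <- match.arg(variant)
  out <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if ("day_of_week" %in% names(out)) {
    out$day_of_week <- factor(out$day_of_week,
                              levels = levels(day_of_week_factor(1)))
  }
  out$participant_id <- as.character(out$participant_id)
  attr(out, "predictors") <- variant_predictors(variant)
  attr(out, "variant") <- variant
  out
}

#' Predictor names attached to a feature table
#'
#' @param features A table from [build_features()].
#' @return Character vector of predictor column names.
#' @export
feature_predictors <- function(features) {
  p <- attr(features, "predictors")
  if (is.null(p)) stop("table has no 'predictors' attribute", call. = FALSE)
  p
}
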