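#' Daily item schema
#'
#' The instrument administered each evening contains ten risk/protective
#' items plus an ideation-frequency item from which the binary outcome is
#' derived. Each item is bounded; `higher_is_risk` records the direction in
#' which the scale points toward elevated risk (self-efficacy and the two
#' connectedness items are protective, so lower values indicate risk).
#'
#' Scale ranges: hopelessness 1-4 (agreement with a hopelessness statement);
#' connectedness to friends / family 1-7; burdensomeness 1-7; agitation 1-7;
#' worry 1-7; rumination 1-7; self-efficacy to refrain from suicidal action
#' 0-10; psychological pain 1-5; ideation duration 0-5 (0 = no ideation,
#' 5 = continuous); ideation frequency 0-4 (0 = not at all, 4 = all the
#' time).
#'
#' @return A tibble with columns `item`, `min`, `max`, `higher_is_risk`.
#' @export
#' @examples
#' item_schema()
item_schema <- function() {
  tibble::tribble(
    ~item,                   ~min, ~max, ~higher_is_risk,
    "hopelessness",             1,    4, TRUE,
    "connectedness_friends",    1,    7, FALSE,
    "connectedness_family",     1,    7, FALSE,
    "burdensomeness",           1,    7, TRUE,
    "agitation",                1,    7, TRUE,
    "worry",                    1,    7, TRUE,
    "rumination",               1,    7, TRUE,
    "self_efficacy",            0,   10, FALSE,
    "psychological_pain",       1,    5, TRUE,
    "ideation_duration",        0,    5, TRUE,
    "ideation_frequency",       0,    4, TRUE
  )
}

#' Names of the ten predictor items
#'
#' All schema items except `ideation_frequency`, which is reserved for the
#' outcome.
#'
#' @return Character vector of length 10.
#' @export
predictor_items <- function() {
  setdiff(item_schema()$item, "ideation_frequency")
}

#' Study configuration
#'
#' Bundles the analysis settings shared across fitting and cross-validation.
#'
#' @param study_length Number of post-discharge days surveyed (default 28).
#' @param alpha Significance level for split selection in the tree learner
#'   (default 0.05); a node is split only if the smallest Bonferroni-adjusted
#'   instability p-value falls below `alpha`.
#' @param k_folds Number of cross-validation folds (default 5).
#' @param n_repetitions Number of repeated cross-validation rounds
#'   (default 10).
#' @param min_node_size Minimum number of observations in a tree node
#'   (default 50).
#' @param trim Fraction of the ordered observations excluded at each end
#'   when maximising the instability statistic (default 0.1).
#' @param rng_seed Base seed for fold construction.
#' @return An object of class `study_config` (a named list).
#' @export
study_config <- function(study_length = 28, alpha = 0.05, k_folds = 5,
                         n_repetitions = 10, min_node_size = 50,
                         trim = 0.1, rng_seed = 1L) {
  stopifnot(alpha > 0, alpha < 1, k_folds >= 2, n_repetitions >= 1,
            study_length >= 2, min_node_size >= 2, trim > 0, trim < 0.5)
  structure(
    list(study_length = as.integer(study_length), alpha = alpha,
         k_folds = as.integer(k_folds),
         n_repetitions = as.integer(n_repetitions),
         min_node_size = as.integer(min_node_size), trim = trim,
         rng_seed = as.integer(rng_seed)),
    class = "study_config"
  )
}

#' Read a study configuration from YAML
#'
#' @param path Path to a YAML file whose keys mirror the arguments of
#'   [study_config()].
#' @return A `study_config`.
#' @export
read_study_config <- function(path) {
  vals <- yaml::read_yaml(path)
  keep <- intersect(names(vals), names(formals(study_config)))
  do.call(study_config, vals[keep])
}

#' Read and validate a daily-diary CSV
#'
#' Expects one row per completed participant-day with columns
#' `participant_id`, `day_index`, and one column per schema item; empty
#' cells are missing responses. Every value is checked against the schema
#' range. Days with no row (or an all-missing row) are materialised as
#' `completed = FALSE` records through `study_length`, so downstream code
#' can compute previous-day-missingness uniformly.
#'
#' @param path CSV file path.
#' @param study_length Days per participant to materialise (default 28).
#' @param schema Item schema tibble, defaults to [item_schema()].
#' @return A tibble of daily records sorted by participant and day, with a
#'   logical `completed` column.
#' @export
read_daily_csv <- function(path, study_length = 28, schema = item_schema()) {
  stopifnot(file.exists(path))
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  required <- c("participant_id", "day_index", schema$item)
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols) > 0) {
    stop("daily CSV is missing required columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  raw$participant_id <- as.character(raw$participant_id)
  raw$day_index <- as.integer(raw$day_index)
  validate_daily_rows(raw, schema, study_length)
  complete_daily_records(raw[required], study_length = study_length,
                         schema = schema)
}

validate_daily_rows <- function(df, schema, study_length) {
  if (any(is.na(df$participant_id)) || any(is.na(df$day_index))) {
    stop("participant_id and day_index must not be missing", call. = FALSE)
  }
  bad_day <- df$day_index < 1 | df$day_index > study_length
  if (any(bad_day)) {
    stop("day_index out of range [1, ", study_length, "] in row(s) ",
         paste(head(which(bad_day), 5), collapse = ", "), call. = FALSE)
  }
  key <- paste(df$participant_id, df$day_index)
  if (anyDuplicated(key)) {
    dup <- key[duplicated(key)][1]
    stop("duplicate (participant, day) record: ", dup, call. = FALSE)
  }
  for (i in seq_len(nrow(schema))) {
    it <- schema$item[i]
    v <- df[[it]]
    bad <- !is.na(v) & (v < schema$min[i] | v > schema$max[i])
    if (any(bad)) {
      j <- which(bad)[1]
      stop(sprintf(
        "value %s out of range [%s, %s] for item '%s' (participant %s, day %s)",
        format(v[j]), schema$min[i], schema$max[i], it,
        df$participant_id[j], df$day_index[j]), call. = FALSE)
    }
  }
  invisible(df)
}

#' Materialise missing survey days as explicit records
#'
#' @param df Daily rows (completed surveys, possibly with item-level NAs).
#' @param study_length Last day index to materialise.
#' @param schema Item schema.
#' @return Tibble with one row per participant-day for days
#'   `1..study_length`; `completed` is `TRUE` only where every schema item
#'   was answered on a row present in `df`. A row with any missing item is
#'   treated as not completed (items are all-or-nothing within a survey) and
#'   its partial responses are dropped.
#' @export
complete_daily_records <- function(df, study_length = 28,
                                   schema = item_schema()) {
  items <- schema$item
  df <- tibble::as_tibble(df)
  df$completed <- rowSums(is.na(df[items])) == 0
  df[!df$completed, items] <- NA_real_
  grid <- tidyr::expand_grid(
    participant_id = unique(df$participant_id),
    day_index = seq_len(study_length)
  )
  out <- dplyr::left_join(grid, df, by = c("participant_id", "day_index"))
  out$completed[is.na(out$completed)] <- FALSE
  dplyr::arrange(out, .data$participant_id, .data$day_index)
}

#' Write a daily-record table to CSV
#'
#' Only completed rows are written (missing days are re-materialised on
#' read), making read/write lossless for completed records.
#'
#' @param records Daily record tibble as returned by [read_daily_csv()] or
#'   [simulate_study()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_daily_csv <- function(records, path) {
  keep <- c("participant_id", "day_index", item_schema()$item)
  out <- dplyr::filter(records, .data$completed)[keep]
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}
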