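# Calibrated synthetic daily-diary generator. Emulates the post-discharge
# monitoring design: ~78 adolescents surveyed for 28 evenings, ~74% survey
# completion, ~39% of completed days with any ideation, participant-level
# heterogeneity via random intercepts, and a tree-structured ground-truth
# rule linking day-t features to day-(t+1) ideation.

#' Ground-truth tree: internal split node
#'
#' @param variable Feature name (see [feature_vocabulary()]).
#' @param threshold Numeric split point; rows with `variable <= threshold`
#'   go left.
#' @param left,right Child nodes ([tree_split()] or [tree_leaf()]).
#' @param na_left Should rows with a missing value go left? Default `TRUE`.
#' @return A `tree_spec` node.
#' @export
tree_split <- function(variable, threshold, left, right, na_left = TRUE) {
  stopifnot(variable %in% feature_vocabulary(), is.numeric(threshold))
  structure(list(is_leaf = FALSE, variable = variable,
                 threshold = threshold, na_left = na_left,
                 left = left, right = right),
            class = "tree_spec")
}

#' Ground-truth tree: leaf
#'
#' @param offset Log-odds offset added for observations in this leaf.
#' @return A `tree_spec` node.
#' @export
tree_leaf <- function(offset) {
  structure(list(is_leaf = TRUE, offset = offset), class = "tree_spec")
}

#' Names a ground-truth tree may split on
#'
#' Per item: the previous-day score (`_prev`), cumulative person-specific
#' mean (`_cm`) and deviation (`_cs`), plus the context indicators.
#'
#' @return Character vector.
#' @export
feature_vocabulary <- function() {
  items <- predictor_items()
  c(paste0(items, "_prev"), paste0(items, "_cm"), paste0(items, "_cs"),
    context_predictors())
}

#' Evaluate a ground-truth tree on a feature data frame
#'
#' @param spec A `tree_spec`.
#' @param df Data frame holding the variables the tree splits on; missing
#'   values follow each node's `na_left` direction.
#' @return Numeric vector of leaf log-odds offsets, one per row.
#' @export
eval_tree_spec <- function(spec, df) {
  out <- rep(NA_real_, nrow(df))
  recurse <- function(node, idx) {
    if (length(idx) == 0) return(invisible(NULL))
    if (node$is_leaf) {
      out[idx] <<- node$offset
      return(invisible(NULL))
    }
    z <- as.numeric(df[[node$variable]][idx])
    go_left <- z <= node$threshold
    go_left[is.na(go_left)] <- node$na_left
    recurse(node$left, idx[go_left])
    recurse(node$right, idx[!go_left])
  }
  recurse(spec, seq_len(nrow(df)))
  out
}

#' Default ground-truth rule
#'
#' A two-split tree placing the signal in cumulative person-specific
#' means: elevated risk when the running burdensomeness mean exceeds 4,
#' strongest when the running hopelessness mean also exceeds 2.5. Offsets
#' span about 2.3 on the log-odds scale, a large but clinically plausible
#' subgroup contrast.
#'
#' @return A `tree_spec`.
#' @export
default_truth_tree <- function() {
  tree_split("burdensomeness_cm", 4,
             left = tree_leaf(-0.9),
             right = tree_split("hopelessness_cm", 2.5,
                                left = tree_leaf(0.2),
                                right = tree_leaf(1.4)))
}

#' A flat (no-signal) ground-truth rule
#'
#' @return A single-leaf `tree_spec` with zero offset, under which the
#'   outcome is independent of all features.
#' @export
flat_truth_tree <- function() tree_leaf(0)

#' Simulation configuration
#'
#' Defaults reproduce the structure of the motivating study: 78
#' participants followed for 28 days, 26% of surveys missed completely at
#' random, and 39% of completed days with any ideation.
#'
#' @param n_participants Number of participants (default 78).
#' @param study_length Days per participant (default 28).
#' @param p_missing Probability a day's survey is missed (default 0.26).
#' @param random_intercept_sd SD of participant random intercepts on the
#'   log-odds scale (default 1).
#' @param item_ar1_rho Within-person day-to-day autocorrelation of the
#'   latent item processes (default 0.5).
#' @param item_person_mean_sd Between-person SD of item means, in raw scale
#'   units (default 1).
#' @param item_innovation_sd Stationary within-person SD of the latent item
#'   processes (default 1).
#' @param truth_tree Ground-truth rule mapping day-`t` features to
#'   day-`t+1` ideation log-odds (default [default_truth_tree()]).
#' @param target_prevalence Desired fraction of completed days with any
#'   ideation (default 0.39); met by solving for an additive calibration
#'   constant by bisection on a large pilot draw.
#' @param missingness_depends_on_ideation If `TRUE`, the missingness odds
#'   on a given day are raised after a previous-day ideation report
#'   (off by default: missingness is completely at random).
#' @param calibration_constant Optional precomputed calibration constant;
#'   when supplied, [simulate_study()] skips the pilot bisection (useful
#'   when drawing many replicates from one configuration).
#' @param rng_seed Integer seed; the same seed yields byte-identical data.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_participants = 78, study_length = 28,
                       p_missing = 0.26, random_intercept_sd = 1,
                       item_ar1_rho = 0.5, item_person_mean_sd = 1,
                       item_innovation_sd = 1,
                       truth_tree = default_truth_tree(),
                       target_prevalence = 0.39,
                       missingness_depends_on_ideation = FALSE,
                       calibration_constant = NULL,
                       rng_seed = 1L) {
  stopifnot(p_missing >= 0, p_missing < 1, random_intercept_sd >= 0,
            abs(item_ar1_rho) < 1, target_prevalence > 0,
            target_prevalence < 1, n_participants >= 1, study_length >= 2,
            inherits(truth_tree, "tree_spec"))
  structure(
    list(n_participants = as.integer(n_participants),
         study_length = as.integer(study_length), p_missing = p_missing,
         random_intercept_sd = random_intercept_sd,
         item_ar1_rho = item_ar1_rho,
         item_person_mean_sd = item_person_mean_sd,
         item_innovation_sd = item_innovation_sd, truth_tree = truth_tree,
         target_prevalence = target_prevalence,
         missingness_depends_on_ideation = missingness_depends_on_ideation,
         calibration_constant = calibration_constant,
         rng_seed = as.integer(rng_seed)),
    class = "sim_config")
}

# AR(1) items evolve as latent Gaussians around person-specific means and
# are observed rounded/clipped to the schema range. Ideation frequency and
# duration are generated from the outcome process instead (duration is 0
# exactly when frequency is 0).
ar1_items <- function() setdiff(predictor_items(), "ideation_duration")

# One full draw at a given calibration constant. Loops over days,
# vectorised across participants; maintains running completed-day sums so
# the ground-truth tree sees exactly the features the analysis computes.
simulate_core <- function(cfg, const, seed) {
  set.seed(seed)
  np <- cfg$n_participants
  len <- cfg$study_length
  schema <- item_schema()
  items9 <- ar1_items()
  rng <- schema[match(items9, schema$item), ]

  b <- rnorm(np, 0, cfg$random_intercept_sd)
  mid <- (rng$min + rng$max) / 2
  pmeans <- matrix(rnorm(np * length(items9),
                         rep(mid, each = np),
                         cfg$item_person_mean_sd),
                   nrow = np)
  pmeans <- pmin(pmax(pmeans, rep(rng$min, each = np)),
                 rep(rng$max, each = np))

  all_items <- c(items9, "ideation_duration", "ideation_frequency")
  cum_sum <- matrix(0, np, length(all_items),
                    dimnames = list(NULL, all_items))
  cum_n <- rep(0L, np)
  latent <- pmeans + cfg$item_innovation_sd * matrix(rnorm(np * length(items9)), np)

  resp <- array(NA_real_, dim = c(np, len, length(all_items)),
                dimnames = list(NULL, NULL, all_items))
  completed <- matrix(FALSE, np, len)
  ideation <- matrix(NA_integer_, np, len)
  eta_next <- rep(const, np) + b  # day-1 linear predictor: no features yet

  innov_sd <- cfg$item_innovation_sd * sqrt(1 - cfg$item_ar1_rho^2)
  for (t in seq_len(len)) {
    if (t > 1) {
      latent <- pmeans + cfg$item_ar1_rho * (latent - pmeans) +
        innov_sd * matrix(rnorm(np * length(items9)), np)
    }
    obs9 <- pmin(pmax(round(latent), rep(rng$min, each = np)),
                 rep(rng$max, each = np))

    si <- rbinom(np, 1, plogis(eta_next))
    ideation[, t] <- si
    freq <- ifelse(si == 1, pmin(4, 1 + stats::rgeom(np, 0.5)), 0)
    dur <- ifelse(si == 1, pmin(5, 1 + stats::rgeom(np, 0.45)), 0)

    p_miss <- rep(cfg$p_missing, np)
    if (cfg$missingness_depends_on_ideation && t > 1) {
      prev_si <- ideation[, t - 1]
      p_miss <- plogis(qlogis(cfg$p_missing) + 0.7 * prev_si)
    }
    comp <- runif(np) >= p_miss
    completed[, t] <- comp

    day_vals <- cbind(obs9, dur, freq)
    colnames(day_vals) <- all_items
    resp[comp, t, ] <- day_vals[comp, , drop = FALSE]
    cum_sum[comp, ] <- cum_sum[comp, , drop = FALSE] +
      day_vals[comp, , drop = FALSE]
    cum_n <- cum_n + as.integer(comp)

    # features through day t drive the day-(t+1) outcome
    if (t < len) {
      cm <- cum_sum / ifelse(cum_n > 0, cum_n, NA_real_)
      fdf <- as.data.frame(cm[, predictor_items(), drop = FALSE])
      names(fdf) <- paste0(predictor_items(), "_cm")
      prev <- day_vals
      prev[!comp, ] <- NA_real_
      for (it in predictor_items()) {
        fdf[[paste0(it, "_prev")]] <- prev[, it]
        fdf[[paste0(it, "_cs")]] <- prev[, it] - fdf[[paste0(it, "_cm")]]
      }
      fdf$prev_day_missing <- as.integer(!comp)
      fdf$study_week <- pmin(ceiling((t + 1) / 7), 4)
      fdf$day_of_week <- as.numeric(day_of_week_factor(t + 1))
      offs <- eval_tree_spec(cfg$truth_tree, fdf)
      eta_next <- const + b + offs
    }
  }
  list(resp = resp, completed = completed, ideation = ideation, b = b)
}

sim_to_records <- function(core, cfg) {
  np <- cfg$n_participants
  len <- cfg$study_length
  ids <- sprintf("P%03d", seq_len(np))
  all_items <- dimnames(core$resp)[[3]]
  out <- tibble::tibble(
    participant_id = rep(ids, each = len),
    day_index = rep(seq_len(len), np)
  )
  for (it in item_schema()$item) {
    out[[it]] <- as.vector(t(core$resp[, , it]))
  }
  out$completed <- as.vector(t(core$completed))
  out
}

realized_prevalence <- function(core) {
  comp <- core$completed
  mean(core$ideation[comp])
}

#' Simulate a daily-diary study
#'
#' Draws a complete synthetic study from a [sim_config()]: participant
#' random intercepts, bounded AR(1) item trajectories around
#' person-specific means, completely-at-random missing survey days, and a
#' next-day ideation outcome whose log-odds are the ground-truth tree
#' evaluated on the running features, plus the participant intercept, plus
#' a calibration constant. The constant is solved by bisection on a large
#' pilot draw (about 50,000 person-days) so the realised completed-day
#' ideation prevalence matches `target_prevalence`. Ideation frequency is 0
#' on ideation-free days and drawn from a truncated geometric on 1..4
#' otherwise; ideation duration is 0 exactly when frequency is 0.
#'
#' @param cfg A [sim_config()].
#' @return A list with `records` (daily-record tibble, one row per
#'   participant-day), and `truth` (ground-truth log: per-participant
#'   intercepts `b`, the `truth_tree`, the `calibration_constant`, and the
#'   realised completed-day prevalence).
#' @export
simulate_study <- function(cfg = sim_config()) {
  const <- cfg$calibration_constant %||% calibrate_constant(cfg)
  core <- simulate_core(cfg, const, seed = cfg$rng_seed)
  records <- sim_to_records(core, cfg)
  list(
    records = records,
    truth = list(
      b = setNames(core$b, sprintf("P%03d", seq_len(cfg$n_participants))),
      truth_tree = cfg$truth_tree,
      calibration_constant = const,
      realized_prevalence = realized_prevalence(core)
    )
  )
}

#' Solve the prevalence-calibration constant
#'
#' Bisection on a pilot draw large enough (>= 50,000 person-days) that the
#' realised completed-day prevalence is a stable function of the constant.
#'
#' @param cfg A [sim_config()].
#' @param tol Bisection tolerance on the prevalence (default 0.002).
#' @return The calibration constant (log-odds scale).
#' @export
calibrate_constant <- function(cfg, tol = 0.002) {
  pilot_n <- max(cfg$n_participants,
                 ceiling(50000 / cfg$study_length))
  pilot_cfg <- cfg
  pilot_cfg$n_participants <- as.integer(pilot_n)
  pilot_seed <- (cfg$rng_seed %% 1000003L) + 77003L
  f <- function(const) {
    realized_prevalence(simulate_core(pilot_cfg, const, seed = pilot_seed)) -
      cfg$target_prevalence
  }
  lo <- -10
  hi <- 10
  f_lo <- f(lo)
  f_hi <- f(hi)
  if (f_lo > 0 || f_hi < 0) {
    stop("target_prevalence is unreachable under this ground-truth tree; ",
         "widen the leaf offsets or adjust the target", call. = FALSE)
  }
  for (i in 1:40) {
    mid <- (lo + hi) / 2
    fm <- f(mid)
    if (abs(fm) < tol) return(mid)
    if (fm > 0) hi <- mid else lo <- mid
  }
  (lo + hi) / 2
}
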