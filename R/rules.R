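# Decision-tool representation: a fitted tree as an explicit, serialisable
# set of root-to-leaf decision rules that partition the feature space, so
# a flagging rule can be audited and applied outside the fitting code.

#' Construct a rule set
#'
#' @param paths List of paths; each path is a list with `conditions` (list
#'   of `list(var, cmp, thr, na_follows)` where `cmp` is one of `"<="`,
#'   `">"`, `"in"`, `"not_in"`), `prediction` (`"SI"` or `"no SI"`), and
#'   optionally `probability`.
#' @param variables Character vector: the variable vocabulary.
#' @param provenance One of `"fitted"`, `"paper_fig1"`, `"paper_fig2"`.
#' @return An object of class `rule_set`.
#' @export
rule_set <- function(paths, variables, provenance = "fitted") {
  stopifnot(length(paths) >= 1, is.character(variables))
  structure(list(provenance = provenance, variables = variables,
                 paths = paths),
            class = "rule_set")
}

condition_holds <- function(cond, value) {
  if (cond$cmp %in% c("in", "not_in")) {
    if (is.na(value)) return(cond$na_follows)
    hit <- as.character(value) %in% cond$thr
    return(if (cond$cmp == "in") hit else !hit)
  }
  v <- suppressWarnings(as.numeric(value))
  if (is.na(v)) return(cond$na_follows)
  if (cond$cmp == "<=") v <= cond$thr else v > cond$thr
}

#' Enumerate a fitted tree's decision rules
#'
#' Depth-first enumeration of root-to-leaf paths; condition order equals
#' split order, and each condition records which branch rows with a
#' missing value follow (the majority branch recorded at fit time).
#' A leaf is labelled `"SI"` when its smoothed event probability is at
#' least 0.5.
#'
#' @param model A fitted [glmm_tree()].
#' @return A `rule_set` whose paths partition the feature space.
#' @export
tree_to_rules <- function(model) {
  stopifnot(inherits(model, "glmm_tree"))
  paths <- list()
  recurse <- function(node, conds, trail) {
    trail <- c(trail, node$node_id)
    if (node$is_leaf) {
      paths[[length(paths) + 1]] <<- list(
        conditions = conds,
        prediction = if (node$probability >= 0.5) "SI" else "no SI",
        probability = node$probability,
        node_trail = trail
      )
      return(invisible(NULL))
    }
    if (!is.null(node$threshold)) {
      left_c <- list(var = node$variable, cmp = "<=",
                     thr = node$threshold, na_follows = node$na_left)
      right_c <- list(var = node$variable, cmp = ">",
                      thr = node$threshold, na_follows = !node$na_left)
    } else {
      left_c <- list(var = node$variable, cmp = "in",
                     thr = node$left_levels, na_follows = node$na_left)
      right_c <- list(var = node$variable, cmp = "not_in",
                      thr = node$left_levels, na_follows = !node$na_left)
    }
    recurse(node$left, c(conds, list(left_c)), trail)
    recurse(node$right, c(conds, list(right_c)), trail)
  }
  recurse(model$tree, list(), integer(0))
  rule_set(paths, variables = model$predictors, provenance = "fitted")
}

#' Apply a rule set to feature rows
#'
#' Evaluates every path on every row; exactly one path must match each row
#' (the paths partition the feature space, with missing values following
#' the recorded majority branches).
#'
#' @param rules A [rule_set()].
#' @param rows Data frame supplying the rule variables.
#' @return Tibble with `path_id`, `prediction`, and `probability` (`NA`
#'   when the source tree carried class labels only).
#' @export
apply_rules <- function(rules, rows) {
  stopifnot(inherits(rules, "rule_set"))
  missing_vars <- setdiff(rules$variables, names(rows))
  if (length(missing_vars) > 0) {
    stop("rows lack rule variables: ",
         paste(missing_vars, collapse = ", "), call. = FALSE)
  }
  n <- nrow(rows)
  out <- tibble::tibble(path_id = rep(NA_integer_, n),
                        prediction = rep(NA_character_, n),
                        probability = rep(NA_real_, n))
  for (i in seq_len(n)) {
    matched <- which(vapply(rules$paths, function(p) {
      all(vapply(p$conditions,
                 function(cond) condition_holds(cond, rows[[cond$var]][i]),
                 logical(1)))
    }, logical(1)))
    if (length(matched) != 1) {
      stop("rule set is not a partition: row ", i, " matched ",
           length(matched), " paths", call. = FALSE)
    }
    p <- rules$paths[[matched]]
    out$path_id[i] <- matched
    out$prediction[i] <- p$prediction
    out$probability[i] <- p$probability %||% NA_real_
  }
  out
}

#' Serialise a rule set to JSON
#'
#' @param rules A [rule_set()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_ruleset_json <- function(rules, path) {
  payload <- list(
    provenance = rules$provenance,
    variables = rules$variables,
    paths = purrr::map(rules$paths, function(p) {
      list(conditions = purrr::map(p$conditions, function(cond) {
             list(var = cond$var, cmp = cond$cmp, thr = cond$thr,
                  na_follows = cond$na_follows)
           }),
           prediction = p$prediction,
           probability = p$probability)
    })
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' Read a rule set from JSON
#'
#' @param path JSON file written by [write_ruleset_json()] (or transcribed
#'   by hand in the same schema).
#' @return A `rule_set`.
#' @export
read_ruleset_json <- function(path) {
  if (!file.exists(path)) {
    stop("rule-set file not found: ", path, call. = FALSE)
  }
  raw <- jsonlite::read_json(path, simplifyVector = FALSE)
  paths <- purrr::map(raw$paths, function(p) {
    list(
      conditions = purrr::map(p$conditions, function(cond) {
        thr <- cond$thr
        thr <- if (cond$cmp %in% c("in", "not_in")) {
          as.character(unlist(thr))
        } else {
          as.numeric(thr)
        }
        list(var = cond$var, cmp = cond$cmp, thr = thr,
             na_follows = isTRUE(cond$na_follows))
      }),
      prediction = p$prediction,
      probability = if (is.null(p$probability)) NULL
                    else as.numeric(p$probability)
    )
  })
  rule_set(paths, variables = as.character(unlist(raw$variables)),
           provenance = raw$provenance %||% "fitted")
}

#' Load a published-tree fixture
#'
#' The package ships synthetic reconstructions of the two published
#' decision trees for next-day suicidal ideation. Only the risk pathway
#' spelled out in the running text of the source report — ideation-duration
#' cumulative mean at most 0.95, hopelessness cumulative mean at most 2.19,
#' burdensomeness cumulative mean above 1.95, and self-efficacy change
#' score at most -1.59, flagging next-day ideation — and each tree's
#' variable vocabulary are faithful transcriptions; the remaining branches
#' and labels are plausible completions (the full figures are not
#' reproduced in text), which is why the fixture files carry a
#' `_synthetic` suffix and class labels without probabilities.
#'
#' @param which `"fig1"` (with ideation duration) or `"fig2"` (excluding
#'   ideation-duration predictors, including study week).
#' @return A `rule_set` with provenance `"paper_fig1"` or `"paper_fig2"`.
#' @export
load_tree_fixture <- function(which = c("fig1", "fig2")) {
  which <- match.arg(which)
  path <- system.file("extdata",
                      paste0("ruleset_", which, "_synthetic.json"),
                      package = "dailycart")
  if (!nzchar(path)) {
    stop("fixture for ", which, " not found; reinstall the package or ",
         "transcribe the published tree into inst/extdata/ using the ",
         "rule-set JSON schema", call. = FALSE)
  }
  read_ruleset_json(path)
}

#' Validate that a rule set partitions the feature space
#'
#' Draws random (complete and partially missing) rows over the rule
#' variables and checks that exactly one path matches each; errors from
#' [apply_rules()] propagate on failure.
#'
#' @param rules A [rule_set()].
#' @param n_rows Number of random probe rows (default 1000).
#' @param seed RNG seed.
#' @return `TRUE`, invisibly, on success.
#' @export
validate_ruleset <- function(rules, n_rows = 1000, seed = 1) {
  set.seed(seed)
  probe <- random_rule_rows(rules, n_rows)
  apply_rules(rules, probe)
  invisible(TRUE)
}

random_rule_rows <- function(rules, n_rows) {
  thr_by_var <- list()
  for (p in rules$paths) {
    for (cond in p$conditions) {
      if (cond$cmp %in% c("<=", ">")) {
        thr_by_var[[cond$var]] <- c(thr_by_var[[cond$var]], cond$thr)
      }
    }
  }
  probe <- purrr::map(rules$variables, function(v) {
    thr <- thr_by_var[[v]]
    centre <- if (is.null(thr)) 0 else mean(thr)
    span <- if (is.null(thr)) 2 else max(1, diff(range(thr)) + 2)
    x <- runif(n_rows, centre - span, centre + span)
    x[runif(n_rows) < 0.1] <- NA  # probe missing-value routing too
    x
  })
  names(probe) <- rules$variables
  tibble::as_tibble(probe)
}

#' @export
print.rule_set <- function(x, ...) {
  cat("Rule set (", x$provenance, "): ", length(x$paths), " paths over ",
      length(x$variables), " variables\n", sep = "")
  for (i in seq_along(x$paths)) {
    p <- x$paths[[i]]
    conds <- if (length(p$conditions) == 0) "(always)" else {
      paste(purrr::map_chr(p$conditions, function(cond) {
        thr <- if (length(cond$thr) > 1) {
          paste0("{", paste(cond$thr, collapse = ","), "}")
        } else {
          format(cond$thr)
        }
        paste(cond$var, cond$cmp, thr)
      }), collapse = " & ")
    }
    prob <- if (is.null(p$probability)) "" else
      sprintf(" (p = %.2f)", p$probability)
    cat(sprintf("  [%d] %s -> %s%s\n", i, conds, p$prediction, prob))
  }
  invisible(x)
}
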