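metric_labels <- c(auc = "AUC", ppv = "PPV", sensitivity = "Sensitivity",
                   specificity = "Specificity")

#' Write a cross-validated performance report
#'
#' Emits, per model variant, the across-repetition mean and standard error
#' of AUC, PPV, sensitivity and specificity, formatted like a published
#' performance-metrics table: means to 2 decimals, standard errors to 3 in
#' parentheses (e.g. `AUC 0.86 (0.002)`).
#'
#' @param summary A tibble with columns `metric`, `mean`, `se` and
#'   optionally `variant` (as returned by [cv_variants()], or the
#'   `summary` element of a [run_cv()] result).
#' @param path Output text file.
#' @return `path`, invisibly.
#' @export
write_metrics_report <- function(summary, path) {
  if (is.null(summary) || nrow(summary) == 0) {
    stop("empty metrics summary; nothing to report", call. = FALSE)
  }
  stopifnot(all(c("metric", "mean") %in% names(summary)))
  if (!"variant" %in% names(summary)) summary$variant <- "model"
  if (!"se" %in% names(summary)) summary$se <- NA_real_
  lines <- c("Performance metrics for models predicting the next-day outcome",
             "")
  for (v in unique(summary$variant)) {
    lines <- c(lines, paste0("model: ", v))
    block <- summary[summary$variant == v, ]
    ord <- match(names(metric_labels), block$metric)
    block <- block[ord[!is.na(ord)], ]
    for (i in seq_len(nrow(block))) {
      se_txt <- if (is.na(block$se[i])) "NA" else
        sprintf("%.3f", block$se[i])
      lines <- c(lines, sprintf("  %s %.2f (%s)",
                                metric_labels[[block$metric[i]]],
                                block$mean[i], se_txt))
    }
    lines <- c(lines, "")
  }
  writeLines(lines, path)
  invisible(path)
}

#' Parse a performance report back into a tibble
#'
#' Inverse of [write_metrics_report()] (to the printed precision); used to
#' verify the report round-trips.
#'
#' @param path Report file path.
#' @return Tibble with `variant`, `metric`, `mean`, `se`.
#' @export
read_metrics_report <- function(path) {
  lines <- readLines(path)
  out <- list()
  variant <- NA_character_
  rx <- "^  (AUC|PPV|Sensitivity|Specificity) ([0-9.]+) \\(([0-9.]+|NA)\\)$"
  for (ln in lines) {
    if (grepl("^model: ", ln)) {
      variant <- sub("^model: ", "", ln)
    } else if (grepl(rx, ln)) {
      lab <- sub(rx, "\\1", ln)
      out[[length(out) + 1]] <- tibble::tibble(
        variant = variant,
        metric = names(metric_labels)[match(lab, metric_labels)],
        mean = as.numeric(sub(rx, "\\2", ln)),
        se = suppressWarnings(as.numeric(sub(rx, "\\3", ln)))
      )
    }
  }
  dplyr::bind_rows(out)
}

#' @exportS3Method generics::tidy
tidy.glmm_tree <- function(x, ...) {
  rules <- tree_to_rules(x)
  purrr::imap(rules$paths, function(p, i) {
    conds <- if (length(p$conditions) == 0) "(root)" else {
      paste(purrr::map_chr(p$conditions, function(cond) {
        thr <- if (length(cond$thr) > 1) {
          paste0("{", paste(cond$thr, collapse = ","), "}")
        } else {
          format(round(as.numeric(cond$thr), 3))
        }
        paste(cond$var, cond$cmp, thr)
      }), collapse = " & ")
    }
    leaf_id <- p$node_trail[length(p$node_trail)]
    leaf <- find_node(x$tree, leaf_id)
    tibble::tibble(leaf_id = leaf_id, rule = conds, n = leaf$n,
                   events = leaf$events, probability = leaf$probability,
                   prediction = p$prediction)
  }) |>
    dplyr::bind_rows()
}

find_node <- function(node, id) {
  if (node$node_id == id) return(node)
  if (node$is_leaf) return(NULL)
  find_node(node$left, id) %||% find_node(node$right, id)
}

#' @exportS3Method generics::glance
glance.glmm_tree <- function(x, ...) {
  tibble::tibble(
    n = x$n, n_leaves = x$n_leaves, sigma_b = x$sigma_b,
    alpha = x$alpha, min_node_size = x$min_node_size,
    log_likelihood = if (length(x$fit_log)) tail(x$fit_log, 1) else NA_real_,
    iterations = length(x$fit_log), converged = x$converged
  )
}

#' Leaf-profile plot for a fitted GLMM tree
#'
#' Shows each leaf's smoothed event probability with its observation
#' count; a compact alternative to drawing the full dendrogram.
#'
#' @param object A fitted [glmm_tree()].
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.glmm_tree <- function(object, ...) {
  leaves <- tidy(object)
  leaves$leaf <- factor(leaves$leaf_id)
  ggplot2::ggplot(leaves,
                  ggplot2::aes(x = .data$leaf, y = .data$probability)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_text(ggplot2::aes(label = paste0("n=", .data$n)),
                       vjust = -0.4, size = 3) +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = "Leaf (pre-order id)",
                  y = "Smoothed event probability",
                  title = "GLMM tree leaf profile") +
    ggplot2::theme_minimal()
}
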