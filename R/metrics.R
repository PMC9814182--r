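#' Area under the ROC curve (Mann-Whitney form)
#'
#' AUC computed as the proportion of (positive, negative) pairs in which
#' the positive scores higher, counting ties as half:
#' `(concordant + 0.5 * tied) / (n_pos * n_neg)`. Equals the trapezoidal
#' integral of the ROC curve.
#'
#' @param scores Numeric predicted scores (higher = more positive).
#' @param labels 0/1 outcome labels.
#' @return AUC in \[0, 1\].
#' @export
#' @examples
#' auc_mw(c(0.9, 0.1), c(1, 0)) # 1
auc_mw <- function(scores, labels) {
  stopifnot(length(scores) == length(labels),
            !anyNA(scores), !anyNA(labels), all(labels %in% c(0, 1)))
  n_pos <- sum(labels == 1)
  n_neg <- sum(labels == 0)
  if (n_pos == 0 || n_neg == 0) {
    stop("AUC requires both outcome classes", call. = FALSE)
  }
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' ROC curve over all candidate cutoffs
#'
#' Candidate cutoffs are the midpoints between adjacent distinct scores
#' plus `-Inf` and `+Inf` sentinels; a row is predicted positive when its
#' score is greater than or equal to the cutoff (inclusive).
#'
#' @inheritParams auc_mw
#' @return A tibble of class `roc_curve` with columns `cutoff`,
#'   `sensitivity`, `specificity`, and attribute `auc`.
#' @export
roc_curve <- function(scores, labels) {
  stopifnot(length(scores) == length(labels),
            !anyNA(scores), !anyNA(labels), all(labels %in% c(0, 1)))
  s <- sort(unique(scores))
  cutoffs <- c(-Inf, if (length(s) > 1) (s[-1] + s[-length(s)]) / 2, Inf)
  n_pos <- sum(labels == 1)
  n_neg <- sum(labels == 0)
  sens <- vapply(cutoffs, function(cc) sum(scores >= cc & labels == 1),
                 numeric(1)) / n_pos
  spec <- vapply(cutoffs, function(cc) sum(scores < cc & labels == 0),
                 numeric(1)) / n_neg
  out <- tibble::tibble(cutoff = cutoffs, sensitivity = sens,
                        specificity = spec)
  attr(out, "auc") <- auc_mw(scores, labels)
  class(out) <- c("roc_curve", class(out))
  out
}

#' Closest-top-left cutoff
#'
#' Selects the probability cutoff minimising the squared ROC distance to
#' the perfect-classification corner,
#' `(1 - sensitivity)^2 + (1 - specificity)^2`. Ties are broken toward the
#' lower (more sensitive) cutoff.
#'
#' @param roc A [roc_curve()] tibble.
#' @return The selected cutoff (numeric scalar).
#' @export
closest_top_left <- function(roc) {
  stopifnot(inherits(roc, "roc_curve"))
  d2 <- (1 - roc$sensitivity)^2 + (1 - roc$specificity)^2
  best <- which(d2 <= min(d2) + 1e-12)
  min(roc$cutoff[best])
}

#' Confusion summary at a cutoff
#'
#' Thresholds scores at `score >= cutoff` (inclusive) and reports counts
#' with the derived rates: sensitivity `tp/(tp+fn)`, specificity
#' `tn/(tn+fp)`, and positive predictive value `tp/(tp+fp)` (`NA` when
#' nothing is predicted positive).
#'
#' @inheritParams auc_mw
#' @param cutoff Probability cutoff.
#' @return One-row tibble with `cutoff`, `tp`, `fp`, `tn`, `fn`,
#'   `sensitivity`, `specificity`, `ppv`.
#' @export
confusion_summary <- function(scores, labels, cutoff) {
  stopifnot(is.finite(cutoff) || is.infinite(cutoff))
  pred <- scores >= cutoff
  tp <- sum(pred & labels == 1)
  fp <- sum(pred & labels == 0)
  tn <- sum(!pred & labels == 0)
  fn <- sum(!pred & labels == 1)
  tibble::tibble(
    cutoff = cutoff, tp = tp, fp = fp, tn = tn, fn = fn,
    sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
    specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_,
    ppv = if (tp + fp > 0) tp / (tp + fp) else NA_real_
  )
}

#' Pooled performance metrics with ROC-selected cutoff
#'
#' Convenience wrapper: computes the AUC, selects the closest-top-left
#' cutoff, and summarises sensitivity, specificity and PPV at that cutoff.
#'
#' @inheritParams auc_mw
#' @return One-row tibble with `auc`, `cutoff`, `sensitivity`,
#'   `specificity`, `ppv`.
#' @export
score_predictions <- function(scores, labels) {
  roc <- roc_curve(scores, labels)
  cut <- closest_top_left(roc)
  cs <- confusion_summary(scores, labels, cut)
  tibble::tibble(auc = attr(roc, "auc"), cutoff = cut,
                 sensitivity = cs$sensitivity,
                 specificity = cs$specificity, ppv = cs$ppv)
}

#' @exportS3Method ggplot2::autoplot
autoplot.roc_curve <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = 1 - .data$specificity,
                               y = .data$sensitivity)) +
    ggplot2::geom_abline(intercept = 0, slope = 1, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_path() +
    ggplot2::coord_equal() +
    ggplot2::labs(
      x = "1 - specificity (false-positive rate)",
      y = "Sensitivity",
      title = sprintf("ROC curve (AUC = %.3f)", attr(object, "auc"))
    ) +
    ggplot2::theme_minimal()
}
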