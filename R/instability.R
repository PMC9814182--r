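# Score-based parameter instability tests used for unbiased split-variable
# selection. The node model is an intercept-only logistic regression with
# per-observation offsets (the current random-intercept values), so the
# score contributions are the 1-dimensional residuals y - p.

#' Tail probability of the trimmed maximally-selected statistic
#'
#' Approximates `P(sup_{t in [t1, t2]} B(t)^2 / (t (1 - t)) > stat)` for a
#' Brownian bridge `B`, via the Miller-Siegmund boundary-crossing
#' approximation for maximally selected statistics. Clamped to \[0, 1\];
#' the approximation is conservative for small statistics.
#'
#' @param stat Observed supremum of the squared standardised bridge.
#' @param t1,t2 Trimming bounds, `0 < t1 < t2 < 1`.
#' @return Approximate p-value.
#' @export
suplm_pvalue <- function(stat, t1, t2) {
  stopifnot(t1 > 0, t2 < 1, t1 <= t2)
  if (stat <= 0) return(1)
  logr <- log((t2 * (1 - t1)) / (t1 * (1 - t2)))
  ms <- function(b) dnorm(b) * ((b - 1 / b) * logr + 4 / b)
  # the approximation is unimodal in b and only valid past its peak;
  # below the peak the true tail is essentially 1, so evaluate at the
  # peak to keep the p-value monotone in the statistic
  b_peak <- stats::optimize(ms, c(0.05, 3), maximum = TRUE)$maximum
  b <- max(sqrt(stat), b_peak)
  min(1, max(ms(b), 2 * stats::pnorm(-b)))  # never below the pointwise tail
}

#' Parameter instability test for an ordered candidate variable
#'
#' Orders the node's score residuals by the candidate, forms the
#' standardised cumulative-sum (empirical fluctuation) process, and takes
#' the supremum of the squared bridge over breakpoints lying between
#' distinct candidate values inside the trimmed range (a supLM-type
#' statistic). Rows where the candidate is missing are ignored.
#'
#' @param z Candidate variable (numeric).
#' @param resid Score residuals `y - p` from the node model (sum to 0 at
#'   the node MLE).
#' @param trim Fraction trimmed at each end (default 0.1).
#' @return List with `statistic` and `p_value` (`p_value = 1` when the
#'   candidate is constant or no admissible breakpoint exists).
#' @export
instability_test_ordered <- function(z, resid, trim = 0.1) {
  ok <- !is.na(z)
  z <- z[ok]
  r <- resid[ok]
  n <- length(z)
  if (n < 10 || length(unique(z)) < 2) {
    return(list(statistic = 0, p_value = 1))
  }
  o <- order(z)
  z <- z[o]
  r <- r[o]
  r <- r - mean(r)  # re-centre within non-missing rows
  j_hat <- sum(r^2)
  if (j_hat <= 0) return(list(statistic = 0, p_value = 1))
  w <- cumsum(r) / sqrt(j_hat)
  tt <- seq_len(n) / n
  from <- max(1L, ceiling(n * trim))
  to <- min(n - 1L, floor(n * (1 - trim)))
  valid <- which(diff(z) > 0)
  valid <- valid[valid >= from & valid <= to]
  if (length(valid) == 0) return(list(statistic = 0, p_value = 1))
  lm_proc <- w[valid]^2 / (tt[valid] * (1 - tt[valid]))
  stat <- max(lm_proc)
  t1 <- min(valid) / n
  t2 <- max(valid) / n
  list(statistic = stat, p_value = suplm_pvalue(stat, t1, t2))
}

#' Parameter instability test for a categorical candidate
#'
#' Chi-square statistic on the per-level sums of score residuals:
#' `sum_l S_l^2 / (n_l * sigma2_hat)` with `L - 1` degrees of freedom
#' (one lost because the residuals sum to zero).
#'
#' @param z Candidate factor.
#' @param resid Score residuals.
#' @return List with `statistic` and `p_value`.
#' @export
instability_test_categorical <- function(z, resid) {
  ok <- !is.na(z)
  z <- droplevels(factor(z[ok]))
  r <- resid[ok]
  n <- length(r)
  if (n < 10 || nlevels(z) < 2) return(list(statistic = 0, p_value = 1))
  r <- r - mean(r)
  sigma2 <- sum(r^2) / n
  if (sigma2 <= 0) return(list(statistic = 0, p_value = 1))
  s_l <- tapply(r, z, sum)
  n_l <- tabulate(z)
  stat <- sum(s_l^2 / n_l) / sigma2
  list(statistic = stat,
       p_value = pchisq(stat, df = nlevels(z) - 1, lower.tail = FALSE))
}

#' Instability test for one candidate (dispatch + Bonferroni happens in the
#' tree learner)
#'
#' @param z Candidate (numeric or factor).
#' @param resid Score residuals.
#' @param trim Trimming fraction for ordered candidates.
#' @return List with `statistic` and `p_value`.
#' @export
instability_test <- function(z, resid, trim = 0.1) {
  if (is.factor(z) || is.character(z)) {
    instability_test_categorical(z, resid)
  } else {
    instability_test_ordered(as.numeric(z), resid, trim = trim)
  }
}
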