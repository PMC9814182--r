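brute_force_auc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  total <- 0
  for (p in pos) for (q in neg) {
    total <- total + (p > q) + 0.5 * (p == q)
  }
  total / (length(pos) * length(neg))
}

test_that("AUC equals the all-pairs Mann-Whitney count", {
  expect_equal(auc_mw(c(0.9, 0.1), c(1, 0)), 1)
  expect_equal(auc_mw(rep(0.5, 10), rep(c(0, 1), 5)), 0.5)
  set.seed(7)
  for (i in 1:25) {
    n <- sample(5:20, 1)
    scores <- round(runif(n), 2)  # rounding forces ties
    labels <- c(0, 1, rbinom(n - 2, 1, 0.5))
    expect_equal(auc_mw(scores, labels), brute_force_auc(scores, labels),
                 tolerance = 1e-12)
  }
  expect_error(auc_mw(c(0.1, 0.2), c(1, 1)), "both")
})

test_that("AUC is invariant to strictly monotone score transforms", {
  set.seed(11)
  scores <- rnorm(40)
  labels <- rbinom(40, 1, 0.4)
  labels[1:2] <- c(0, 1)
  a <- auc_mw(scores, labels)
  expect_equal(auc_mw(exp(scores), labels), a)
  expect_equal(auc_mw(qlogis(plogis(scores)), labels), a, tolerance = 1e-12)
})

test_that("trapezoidal ROC area equals the Mann-Whitney statistic", {
  set.seed(13)
  for (i in 1:10) {
    scores <- round(rnorm(30), 1)
    labels <- c(0, 1, rbinom(28, 1, 0.4))
    roc <- roc_curve(scores, labels)
    fpr <- rev(1 - roc$specificity)
    tpr <- rev(roc$sensitivity)
    trap <- sum(diff(fpr) * (head(tpr, -1) + tail(tpr, -1)) / 2)
    expect_equal(trap, auc_mw(scores, labels), tolerance = 1e-12)
  }
})

test_that("closest-top-left matches exhaustive search and geometry", {
  # perfectly separable: selected cutoff classifies perfectly
  scores <- c(0.9, 0.8, 0.2, 0.1)
  labels <- c(1, 1, 0, 0)
  roc <- roc_curve(scores, labels)
  cut <- closest_top_left(roc)
  cs <- confusion_summary(scores, labels, cut)
  expect_equal(cs$sensitivity, 1)
  expect_equal(cs$specificity, 1)

  set.seed(17)
  for (i in 1:10) {
    scores <- round(runif(15), 2)
    labels <- c(0, 1, rbinom(13, 1, 0.5))
    roc <- roc_curve(scores, labels)
    cut <- closest_top_left(roc)
    # brute force over every candidate cutoff
    d2 <- vapply(roc$cutoff, function(cc) {
      cs <- confusion_summary(scores, labels, cc)
      (1 - cs$sensitivity)^2 + (1 - cs$specificity)^2
    }, numeric(1))
    expect_equal(min(d2),
                 (1 - confusion_summary(scores, labels, cut)$sensitivity)^2 +
                   (1 - confusion_summary(scores, labels, cut)$specificity)^2,
                 tolerance = 1e-12)
    # tie-break: no better candidate strictly below the chosen cutoff
    ties <- roc$cutoff[d2 <= min(d2) + 1e-12]
    expect_equal(cut, min(ties))
  }
})

test_that("confusion summary arithmetic matches hand counts", {
  scores <- c(0.9, 0.8, 0.2, 0.1)
  labels <- c(1, 1, 0, 0)
  cs <- confusion_summary(scores, labels, 0.5)
  expect_equal(cs[c("tp", "fp", "tn", "fn")],
               tibble::tibble(tp = 2L, fp = 0L, tn = 2L, fn = 0L),
               ignore_attr = TRUE)
  expect_equal(cs$ppv, 1)

  scores10 <- c(0.9, 0.85, 0.7, 0.65, 0.6, 0.4, 0.35, 0.3, 0.2, 0.1)
  labels10 <- c(1, 0, 1, 1, 0, 1, 0, 0, 0, 0)
  cs10 <- confusion_summary(scores10, labels10, 0.5)
  expect_equal(cs10$tp, 3)   # 0.9, 0.7, 0.65
  expect_equal(cs10$fp, 2)   # 0.85, 0.6
  expect_equal(cs10$ppv, 3 / 5)
  expect_equal(cs10$sensitivity, 3 / 4)
  expect_equal(cs10$specificity, 4 / 6)

  all_neg <- confusion_summary(scores, labels, 2)
  expect_equal(all_neg$sensitivity, 0)
  expect_true(is.na(all_neg$ppv))
})

test_that("PPV rises with outcome prevalence at fixed sens/spec", {
  # duplicate positives to raise prevalence without moving the ROC point
  scores <- c(0.9, 0.8, 0.3, 0.6, 0.2, 0.1)
  labels <- c(1, 1, 1, 0, 0, 0)
  low <- confusion_summary(scores, labels, 0.5)
  rich <- confusion_summary(c(scores, scores[labels == 1]),
                            c(labels, rep(1, 3)), 0.5)
  expect_equal(rich$sensitivity, low$sensitivity)
  expect_equal(rich$specificity, low$specificity)
  expect_gt(rich$ppv, low$ppv)
})

test_that("AUC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(23)
  scores <- rnorm(60)
  labels <- rbinom(60, 1, 0.4)
  labels[1:2] <- c(0, 1)
  ref <- suppressMessages(as.numeric(pROC::auc(labels, scores,
                                               direction = "<")))
  expect_equal(auc_mw(scores, labels), ref, tolerance = 1e-12)
})
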