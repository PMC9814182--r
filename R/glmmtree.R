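# GLMM tree learner: model-based recursive partitioning for a binary
# outcome with participant random intercepts. Fitting alternates between
# (i) growing a tree on the log-odds scale, holding each observation's
# random-intercept value fixed as an offset, and (ii) refitting a
# random-intercept logistic model with the leaf memberships as fixed
# effects (lme4::glmer, Laplace approximation) to update the intercepts.

# ---- node-level logistic helpers -------------------------------------------

# Intercept-only logistic MLE with offsets; returns the intercept.
node_intercept <- function(y, offset) {
  if (all(y == y[1])) return(if (y[1] == 1) 15 else -15)
  b <- qlogis(mean(y)) - mean(offset)
  for (i in 1:50) {
    p <- plogis(b + offset)
    g <- sum(y - p)
    h <- sum(p * (1 - p))
    if (h < 1e-12) break
    step <- g / h
    b <- min(15, max(-15, b + step))
    if (abs(step) < 1e-10) break
  }
  b
}

node_loglik <- function(y, offset) {
  n <- length(y)
  if (n == 0) return(0)
  same_off <- diff(range(offset)) < 1e-12
  if (same_off) {
    k <- sum(y)
    ll <- 0
    if (k > 0) ll <- ll + k * log(k / n)
    if (k < n) ll <- ll + (n - k) * log(1 - k / n)
    return(ll)
  }
  b <- node_intercept(y, offset)
  p <- plogis(b + offset)
  sum(y * log(pmax(p, 1e-12)) + (1 - y) * log(pmax(1 - p, 1e-12)))
}

# ---- split search ----------------------------------------------------------

# Best threshold for an ordered variable: exhaustive over midpoints of
# adjacent distinct values (quantile-thinned to <= max_candidates for
# continuous variables), maximising the two children's binomial
# log-likelihoods under the current offsets, subject to min_node_size.
# Rows with a missing candidate follow the larger (majority) child.
best_split_ordered <- function(z, y, offset, min_node, max_candidates = 100) {
  ok <- !is.na(z)
  n_na <- sum(!ok)
  zs <- sort(unique(z[ok]))
  if (length(zs) < 2) return(NULL)
  mids <- (zs[-1] + zs[-length(zs)]) / 2
  if (length(mids) > max_candidates) {
    idx <- unique(round(seq(1, length(mids), length.out = max_candidates)))
    mids <- mids[idx]
  }
  best <- NULL
  for (thr in mids) {
    left <- ok & z <= thr
    right <- ok & z > thr
    na_left <- sum(left) >= sum(right)
    n_left <- sum(left) + if (na_left) n_na else 0L
    n_right <- sum(right) + if (na_left) 0L else n_na
    if (n_left < min_node || n_right < min_node) next
    li <- if (na_left) left | !ok else left
    ri <- if (na_left) right else right | !ok
    ll <- node_loglik(y[li], offset[li]) + node_loglik(y[ri], offset[ri])
    if (is.null(best) || ll > best$loglik + 1e-12) {
      best <- list(threshold = thr, na_left = na_left, loglik = ll,
                   left_idx = li, right_idx = ri)
    }
  }
  best
}

# Best level subset for a categorical variable: levels ordered by mean
# score residual, then scanned as contiguous prefixes (the classical CART
# shortcut, exact for binary outcomes without offsets).
best_split_categorical <- function(z, y, offset, resid, min_node) {
  ok <- !is.na(z)
  n_na <- sum(!ok)
  zf <- droplevels(factor(z[ok]))
  if (nlevels(zf) < 2) return(NULL)
  mr <- tapply(resid[ok], zf, mean)
  ord <- names(sort(mr))
  best <- NULL
  for (j in seq_len(length(ord) - 1)) {
    lev_left <- ord[seq_len(j)]
    left <- ok & as.character(z) %in% lev_left
    right <- ok & !(as.character(z) %in% lev_left)
    na_left <- sum(left) >= sum(right)
    n_left <- sum(left) + if (na_left) n_na else 0L
    n_right <- sum(right) + if (na_left) 0L else n_na
    if (n_left < min_node || n_right < min_node) next
    li <- if (na_left) left | !ok else left
    ri <- if (na_left) right else right | !ok
    ll <- node_loglik(y[li], offset[li]) + node_loglik(y[ri], offset[ri])
    if (is.null(best) || ll > best$loglik + 1e-12) {
      best <- list(left_levels = lev_left, na_left = na_left, loglik = ll,
                   left_idx = li, right_idx = ri)
    }
  }
  best
}

# ---- tree growth -----------------------------------------------------------

grow_tree <- function(data, y, offset, predictors, alpha, min_node, trim) {
  n <- length(y)
  make_leaf <- function(y) {
    k <- sum(y)
    n <- length(y)
    list(is_leaf = TRUE, n = n, events = k,
         probability = (k + 0.5) / (n + 1))
  }
  if (n < 2 * min_node || length(unique(y)) < 2) return(make_leaf(y))

  beta0 <- node_intercept(y, offset)
  resid <- y - plogis(beta0 + offset)

  tests <- purrr::map(predictors, function(v) {
    z <- data[[v]]
    if (length(unique(z[!is.na(z)])) < 2) {
      list(statistic = 0, p_value = 1, tested = FALSE)
    } else {
      c(instability_test(z, resid, trim = trim), tested = TRUE)
    }
  })
  names(tests) <- predictors
  m <- sum(purrr::map_lgl(tests, "tested"))
  if (m == 0) return(make_leaf(y))
  p_adj <- purrr::map_dbl(tests, ~ min(1, .x$p_value * m))
  # lowest adjusted p wins; ties go to the earliest declared predictor
  best_var <- predictors[which.min(p_adj)]
  if (p_adj[[best_var]] >= alpha) return(make_leaf(y))

  z <- data[[best_var]]
  split <- if (is.factor(z) || is.character(z)) {
    best_split_categorical(z, y, offset, resid, min_node)
  } else {
    best_split_ordered(as.numeric(z), y, offset, min_node)
  }
  if (is.null(split)) return(make_leaf(y))

  li <- split$left_idx
  ri <- split$right_idx
  node <- list(
    is_leaf = FALSE, variable = best_var, na_left = split$na_left,
    p_value = unname(p_adj[[best_var]]),
    statistic = tests[[best_var]]$statistic, n = n,
    left = grow_tree(data[li, , drop = FALSE], y[li], offset[li],
                     predictors, alpha, min_node, trim),
    right = grow_tree(data[ri, , drop = FALSE], y[ri], offset[ri],
                      predictors, alpha, min_node, trim)
  )
  if (!is.null(split$threshold)) {
    node$threshold <- split$threshold
  } else {
    node$left_levels <- split$left_levels
  }
  node
}

number_nodes <- function(node, next_id = 1L) {
  node$node_id <- next_id
  next_id <- next_id + 1L
  if (!node$is_leaf) {
    res <- number_nodes(node$left, next_id)
    node$left <- res$node
    res <- number_nodes(node$right, res$next_id)
    node$right <- res$node
    next_id <- res$next_id
  }
  list(node = node, next_id = next_id)
}

route_rows <- function(node, data) {
  n <- nrow(data)
  out <- rep(NA_integer_, n)
  probs <- rep(NA_real_, n)
  recurse <- function(node, idx) {
    if (length(idx) == 0) return(invisible(NULL))
    if (node$is_leaf) {
      out[idx] <<- node$node_id
      probs[idx] <<- node$probability
      return(invisible(NULL))
    }
    z <- data[[node$variable]][idx]
    if (!is.null(node$threshold)) {
      go_left <- as.numeric(z) <= node$threshold
    } else {
      go_left <- as.character(z) %in% node$left_levels
    }
    go_left[is.na(go_left)] <- node$na_left
    recurse(node$left, idx[go_left])
    recurse(node$right, idx[!go_left])
  }
  recurse(node, seq_len(n))
  list(leaf = out, probability = probs)
}

tree_signature <- function(node) {
  if (node$is_leaf) return("leaf")
  thr <- if (!is.null(node$threshold)) {
    format(node$threshold, digits = 10)
  } else {
    paste(node$left_levels, collapse = "|")
  }
  paste0("(", node$variable, "@", thr, " ",
         tree_signature(node$left), " ", tree_signature(node$right), ")")
}

count_leaves <- function(node) {
  if (node$is_leaf) return(1L)
  count_leaves(node$left) + count_leaves(node$right)
}

# ---- mixed-model refit -----------------------------------------------------

refit_random_intercepts <- function(y, leaf, pid) {
  df <- data.frame(y = y, leaf = factor(leaf), pid = factor(pid))
  ctrl <- lme4::glmerControl(calc.derivs = FALSE,
                             check.conv.singular = "ignore")
  form <- if (nlevels(df$leaf) > 1) {
    y ~ 0 + leaf + (1 | pid)
  } else {
    y ~ 1 + (1 | pid)
  }
  fit <- suppressMessages(suppressWarnings(
    lme4::glmer(form, data = df, family = stats::binomial, control = ctrl)
  ))
  re <- lme4::ranef(fit)$pid
  b <- setNames(re[[1]], rownames(re))
  sigma_b <- sqrt(as.numeric(lme4::VarCorr(fit)$pid[1]))
  list(b = b, sigma_b = sigma_b, loglik = as.numeric(logLik(fit)))
}

# ---- main fitting routine --------------------------------------------------

#' Fit a GLMM tree to a feature table
#'
#' Grows a model-based classification tree for a binary outcome while
#' accounting for within-participant dependence through random intercepts.
#' At each node, an intercept-only logistic model is fitted (with the
#' current random-intercept values as offsets) and a score-based parameter
#' instability test is run for every candidate predictor (supLM-type for
#' ordered variables, chi-square for categorical). P-values are Bonferroni
#' adjusted across the candidates tested at the node, and the node is split
#' on the variable with the smallest adjusted p-value if it falls below
#' `alpha`; the split point maximises the children's binomial
#' log-likelihoods. After each tree is grown, a random-intercept logistic
#' model with leaf memberships as fixed effects is estimated by Laplace
#' approximation ([lme4::glmer()]) and the updated intercepts are fed back
#' as offsets; the alternation stops when the mixed-model log-likelihood
#' changes by less than `tol` or after `max_iter` rounds.
#'
#' Missing predictor values follow the majority branch recorded at fit
#' time; leaf probabilities are smoothed empirical rates
#' `(events + 0.5) / (n + 1)`.
#'
#' @param features Feature table from [build_features()] (or any data
#'   frame with an `outcome` column and a `participant_id` column).
#' @param predictors Character vector of predictor columns; defaults to the
#'   table's `"predictors"` attribute.
#' @param config A [study_config()] supplying `alpha`, `min_node_size` and
#'   `trim`.
#' @param max_iter Maximum alternation rounds (default 100).
#' @param tol Convergence tolerance on the mixed-model log-likelihood
#'   (default 1e-4).
#' @return An object of class `glmm_tree`: the tree, `sigma_b`, the
#'   per-participant intercepts (`ranef`), the iteration log-likelihood
#'   trace (`fit_log`), and a `converged` flag.
#' @export
glmm_tree <- function(features, predictors = NULL, config = study_config(),
                      max_iter = 100, tol = 1e-4) {
  predictors <- predictors %||% attr(features, "predictors")
  if (is.null(predictors)) {
    stop("no predictors given and table has no 'predictors' attribute",
         call. = FALSE)
  }
  missing_cols <- setdiff(c("outcome", "participant_id", predictors),
                          names(features))
  if (length(missing_cols) > 0) {
    stop("feature table lacks columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  y <- features$outcome
  stopifnot(!anyNA(y), all(y %in% c(0, 1)))
  pid <- as.character(features$participant_id)
  n <- length(y)
  if (n < config$min_node_size) {
    stop("fewer rows than min_node_size", call. = FALSE)
  }

  new_fit <- function(root, sigma_b, b, fit_log, converged, single_class) {
    root <- number_nodes(root)$node
    structure(
      list(tree = root, sigma_b = sigma_b, ranef = b,
           alpha = config$alpha, min_node_size = config$min_node_size,
           trim = config$trim, predictors = predictors,
           predictor_classes = purrr::map_chr(features[predictors],
                                              ~ class(.x)[1]),
           n = n, n_leaves = count_leaves(root), fit_log = fit_log,
           converged = converged, single_class = single_class),
      class = "glmm_tree")
  }

  if (length(unique(y)) < 2) {
    warning("outcome has a single class; returning a root-only model",
            call. = FALSE)
    k <- sum(y)
    root <- list(is_leaf = TRUE, n = n, events = k,
                 probability = (k + 0.5) / (n + 1))
    return(new_fit(root, 0, setNames(rep(0, length(unique(pid))),
                                     unique(pid)),
                   numeric(0), TRUE, TRUE))
  }

  offset <- rep(0, n)
  b <- setNames(rep(0, length(unique(pid))), unique(pid))
  sigma_b <- 0
  fit_log <- numeric(0)
  converged <- FALSE
  prev_ll <- -Inf
  root <- NULL
  for (iter in seq_len(max_iter)) {
    root <- grow_tree(features[predictors], y, offset, predictors,
                      config$alpha, config$min_node_size, config$trim)
    root <- number_nodes(root)$node
    leaf <- route_rows(root, features[predictors])$leaf
    mm <- refit_random_intercepts(y, leaf, pid)
    b <- mm$b
    sigma_b <- mm$sigma_b
    fit_log <- c(fit_log, mm$loglik)
    if (abs(mm$loglik - prev_ll) < tol) {
      converged <- TRUE
      break
    }
    prev_ll <- mm$loglik
    offset <- unname(b[pid])
  }
  if (!converged && max_iter > 1) {
    warning("GLMM tree alternation did not converge; returning last iterate",
            call. = FALSE)
  }
  new_fit(root, sigma_b, b, fit_log, converged, FALSE)
}

#' Predict event probabilities from a GLMM tree
#'
#' Routes each row to its leaf (missing values follow the majority branch
#' recorded at fit time) and returns the leaf probability. With
#' `use_random_effects = TRUE`, a known participant's random intercept is
#' added on the log-odds scale; unseen participants always receive the
#' population-level leaf probability (`b = 0`), which is also the rule used
#' for test folds in blocked cross-validation.
#'
#' @param object A fitted `glmm_tree`.
#' @param newdata Data frame containing the model's predictor columns (and
#'   `participant_id` if `use_random_effects`).
#' @param use_random_effects Add known participants' random intercepts?
#'   Default `FALSE`.
#' @param ... Unused.
#' @return Numeric vector of event probabilities.
#' @export
predict.glmm_tree <- function(object, newdata,
                              use_random_effects = FALSE, ...) {
  missing_cols <- setdiff(object$predictors, names(newdata))
  if (length(missing_cols) > 0) {
    stop("newdata lacks predictor columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  routed <- route_rows(object$tree, newdata[object$predictors])
  p <- routed$probability
  if (use_random_effects && "participant_id" %in% names(newdata)) {
    b <- unname(object$ranef[as.character(newdata$participant_id)])
    b[is.na(b)] <- 0
    p <- plogis(qlogis(p) + b)
  }
  unname(p)
}

#' @export
print.glmm_tree <- function(x, ...) {
  cat("GLMM tree:", x$n_leaves, "leaves,", x$n, "observations\n")
  cat(sprintf("random-intercept SD (sigma_b): %.3f\n", x$sigma_b))
  cat(sprintf("splitting alpha: %g (Bonferroni-adjusted), min node size: %d\n",
              x$alpha, x$min_node_size))
  print_node <- function(node, indent) {
    pad <- strrep("  ", indent)
    if (node$is_leaf) {
      cat(sprintf("%s[%d] leaf: p = %.3f (%d/%d)\n", pad, node$node_id,
                  node$probability, node$events, node$n))
    } else {
      cond <- if (!is.null(node$threshold)) {
        sprintf("%s <= %.3f", node$variable, node$threshold)
      } else {
        sprintf("%s in {%s}", node$variable,
                paste(node$left_levels, collapse = ","))
      }
      cat(sprintf("%s[%d] %s (p = %.2g)\n", pad, node$node_id, cond,
                  node$p_value))
      print_node(node$left, indent + 1)
      print_node(node$right, indent + 1)
    }
  }
  print_node(x$tree, 0)
  invisible(x)
}
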