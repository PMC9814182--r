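test_that("path enumeration matches the tree's leaf count", {
  fit <- fitted_small_tree()
  rules <- tree_to_rules(fit)
  expect_equal(length(rules$paths), fit$n_leaves)

  # root-only model gives one unconditional path
  root_fit <- root_only_fit()
  expect_equal(root_fit$n_leaves, 1L)
  root_rules <- tree_to_rules(root_fit)
  expect_length(root_rules$paths, 1)
  expect_length(root_rules$paths[[1]]$conditions, 0)
  expect_equal(apply_rules(root_rules, features_null()[1:5, ])$probability,
               rep(root_fit$tree$probability, 5))
})

test_that("rule evaluation reproduces tree-traversal predictions", {
  fit <- fitted_small_tree()
  rules <- tree_to_rules(fit)
  set.seed(29)
  probe <- random_probe_rows(fit, 1000)
  via_tree <- predict(fit, probe)
  via_rules <- apply_rules(rules, probe)$probability
  expect_equal(via_rules, via_tree, tolerance = 1e-12)
})

test_that("rule sets survive a JSON round-trip", {
  fit <- fitted_small_tree()
  rules <- tree_to_rules(fit)
  path <- withr::local_tempfile(fileext = ".json")
  write_ruleset_json(rules, path)
  back <- read_ruleset_json(path)
  expect_equal(back$variables, rules$variables)
  set.seed(31)
  probe <- random_probe_rows(fit, 500)
  expect_equal(apply_rules(back, probe), apply_rules(rules, probe))
})

test_that("the published-tree fixture carries the stated risk pathway", {
  fig1 <- load_tree_fixture("fig1")
  target <- list(
    list(var = "ideation_duration_cm", cmp = "<=", thr = 0.95),
    list(var = "hopelessness_cm", cmp = "<=", thr = 2.19),
    list(var = "burdensomeness_cm", cmp = ">", thr = 1.95),
    list(var = "self_efficacy_cs", cmp = "<=", thr = -1.59)
  )
  match_path <- purrr::detect(fig1$paths, function(p) {
    length(p$conditions) == length(target) &&
      all(purrr::map2_lgl(p$conditions, target, function(a, b) {
        a$var == b$var && a$cmp == b$cmp &&
          isTRUE(all.equal(a$thr, b$thr))
      }))
  })
  expect_false(is.null(match_path))
  expect_equal(match_path$prediction, "SI")

  # the quoted example row flags next-day ideation via that pathway
  row <- tibble::tibble(ideation_duration_cm = 0.5, hopelessness_cm = 2.0,
                        burdensomeness_cm = 2.5, self_efficacy_cs = -2.0)
  expect_equal(apply_rules(fig1, row)$prediction, "SI")
})

test_that("the duration-free fixture swaps duration for study week", {
  fig2 <- load_tree_fixture("fig2")
  expect_false(any(grepl("ideation_duration", fig2$variables)))
  expect_true("study_week" %in% fig2$variables)
  expect_setequal(fig2$variables,
                  c("burdensomeness_cm", "hopelessness_cm",
                    "self_efficacy_cs", "study_week"))
})

test_that("both fixtures partition the feature space", {
  for (which in c("fig1", "fig2")) {
    rules <- load_tree_fixture(which)
    expect_true(validate_ruleset(rules, n_rows = 10000, seed = 37))
  }
})

test_that("a row outside every stated risk path lands in the safe region", {
  fig1 <- load_tree_fixture("fig1")
  row <- tibble::tibble(ideation_duration_cm = 0.2, hopelessness_cm = 1.0,
                        burdensomeness_cm = 1.0, self_efficacy_cs = 0)
  expect_equal(apply_rules(fig1, row)$prediction, "no SI")
})

test_that("a non-partitioning rule set is rejected", {
  broken <- rule_set(
    paths = list(list(
      conditions = list(list(var = "x", cmp = "<=", thr = 0,
                             na_follows = TRUE)),
      prediction = "SI", probability = NULL)),
    variables = "x")
  expect_error(apply_rules(broken, tibble::tibble(x = 1)),
               "not a partition")
})
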