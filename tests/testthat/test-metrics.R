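test_that("out-of-sample R-squared matches hand-computed cases", {
  y <- c(0, 1, 2)
  expect_equal(r_squared(y, y), 1)
  expect_equal(r_squared(y, rep(mean(y), 3)), 0)
  expect_equal(r_squared(y, c(0, 0, 0)), -1.5)  # SS_res 5, SS_tot 2
  expect_error(r_squared(c(1, 1, 1), c(1, 2, 3)), "identical")
  # never exceeds 1
  for (i in 1:20) {
    yt <- rnorm(10)
    expect_lte(r_squared(yt, rnorm(10)), 1)
  }
})

test_that("rank AUC matches brute-force pair enumeration", {
  expect_equal(auc_rank(c(1, 0), c(0.9, 0.1)), 1)
  expect_equal(auc_rank(c(1, 0), c(0.1, 0.9)), 0)
  expect_equal(auc_rank(c(1, 0, 1, 0), c(0.8, 0.8, 0.2, 0.2)), 0.5)
  set.seed(404)
  for (i in 1:30) {
    n <- sample(4:30, 1)
    y <- c(0, 1, rbinom(n - 2, 1, 0.5))      # both classes guaranteed
    s <- sample(seq(0, 1, by = 0.1), n, replace = TRUE)  # ties likely
    expect_equal(auc_rank(y, s), auc_bruteforce(y, s))
  }
  expect_error(auc_rank(c(1, 1), c(0.2, 0.3)), "single-class")
})

test_that("AUC is rank-invariant and antisymmetric in the scores", {
  set.seed(405)
  y <- c(0, 1, rbinom(18, 1, 0.5))
  s <- rnorm(20)
  expect_equal(auc_rank(y, s), auc_rank(y, exp(s)))          # monotone map
  expect_equal(auc_rank(y, s) + auc_rank(y, -s), 1)          # no ties
})

test_that("balanced accuracy matches the confusion-matrix definition", {
  y <- c(1, 1, 0, 0)
  s <- c(0.9, 0.1, 0.2, 0.3)  # predicted classes 1,0,0,0
  expect_equal(balanced_accuracy(y, s), (0.5 + 1) / 2)
  expect_equal(balanced_accuracy(y, c(0.9, 0.8, 0.1, 0.2)), 1)
  expect_equal(balanced_accuracy(y, c(0.9, 0.9, 0.9, 0.9)), 0.5)
  # prevalence invariance: duplicating one class's rows changes nothing
  set.seed(406)
  y2 <- rep(c(0, 1), each = 10)
  s2 <- runif(20)
  dup <- c(y2, rep(0, 10))
  sdup <- c(s2, s2[1:10])
  expect_equal(balanced_accuracy(dup, sdup), balanced_accuracy(y2, s2))
})

test_that("rank AUC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(407)
  y <- c(0, 1, rbinom(28, 1, 0.3))
  s <- round(runif(30), 1)
  ref <- as.numeric(pROC::auc(pROC::roc(y, s, quiet = TRUE,
                                        direction = "<")))
  expect_equal(auc_rank(y, s), ref)
})

test_that("exclusion rules fire in precedence order", {
  expect_equal(exclusion_status(rep(0, 5), runif(5), "classification"),
               "DEGENERATE_TEST_TRUTH")
  # truth check takes precedence over constant predictions
  expect_equal(exclusion_status(rep(1, 5), rep(0.9, 5), "classification"),
               "DEGENERATE_TEST_TRUTH")
  expect_equal(exclusion_status(c(0, 1, 0), c(0.8, 0.9, 0.7), "classification"),
               "CONSTANT_PREDICTION")
  expect_equal(exclusion_status(c(0, 1, 0), c(0.2, 0.9, 0.1), "classification"),
               "INCLUDED")
  # regression analog: zero-variance predictions
  expect_equal(exclusion_status(c(0.1, 1.2, 2.3), rep(0.7, 3), "regression"),
               "CONSTANT_PREDICTION")
  expect_equal(exclusion_status(c(0.1, 1.2, 2.3), c(0.5, 0.6, 0.7), "regression"),
               "INCLUDED")
})

test_that("metrics reports carry task-appropriate fields", {
  rep_c <- metrics_report(c(0.5, -1, 2), c(0.1, 0.2, 0.3), "regression")
  expect_true(is.numeric(rep_c$r2))
  expect_null(rep_c$auc)
  rep_b <- metrics_report(c(0, 1, 0, 1), c(0.1, 0.9, 0.6, 0.2),
                          "classification")
  expect_null(rep_b$r2)
  expect_true(rep_b$auc >= 0 && rep_b$auc <= 1)
  expect_true(rep_b$balanced_accuracy >= 0 && rep_b$balanced_accuracy <= 1)
  expect_equal(unname(rep_b$predicted_class_counts), c(2, 2))
  # excluded runs keep NA metrics rather than misleading numbers
  rep_x <- metrics_report(rep(1, 4), runif(4), "classification")
  expect_equal(rep_x$exclusion, "DEGENERATE_TEST_TRUTH")
  expect_true(is.na(rep_x$auc))
})

test_that("criteria are inclusive at the boundary and nest across thresholds", {
  rep_b <- metrics_report(c(0, 0, 1, 1), c(0.1, 0.9, 0.6, 0.2),
                          "classification")
  rep_b$balanced_accuracy <- 0.6
  rep_b$auc <- 0.59
  flags <- evaluate_criteria(rep_b, default_criteria("binary"))
  expect_true(flags[["BA>=0.6"]])     # inclusive boundary
  expect_false(flags[["AUC>=0.6"]])
  # nesting: DE at a higher threshold implies DE at every lower one
  set.seed(408)
  for (i in 1:25) {
    y <- c(0, 1, rbinom(8, 1, 0.5))
    r <- metrics_report(y, runif(10), "classification")
    f <- evaluate_criteria(r, default_criteria("binary"))
    if (r$exclusion != "INCLUDED") next
    expect_true(!f[["AUC>=0.7"]] || f[["AUC>=0.65"]])
    expect_true(!f[["AUC>=0.65"]] || f[["AUC>=0.6"]])
    expect_true(!f[["BA>=0.7"]] || f[["BA>=0.65"]])
    expect_true(!f[["BA>=0.65"]] || f[["BA>=0.6"]])
  }
})

test_that("criteria refuse metrics foreign to the task", {
  rep_c <- metrics_report(c(0.5, -1, 2), c(0.1, 0.2, 0.3), "regression")
  expect_true(evaluate_criteria(rep_c, de_criterion("R2", 0.1))[[1]] ==
                (rep_c$r2 >= 0.1))
  expect_error(evaluate_criteria(rep_c, de_criterion("AUC", 0.6)),
               "does not apply")
  rep_b <- metrics_report(c(0, 1), c(0.2, 0.9), "classification")
  expect_error(evaluate_criteria(rep_b, de_criterion("R2", 0.1)),
               "does not apply")
})

test_that("excluded reports yield NA flags and JSON records parse", {
  rep_x <- metrics_report(rep(0, 5), runif(5), "classification")
  flags <- evaluate_criteria(rep_x, default_criteria("binary"))
  expect_true(all(is.na(flags)))
  line <- metrics_to_json(rep_x, extra = list(seed = 42))
  parsed <- jsonlite::fromJSON(line)
  expect_equal(parsed$seed, 42)
  expect_equal(parsed$exclusion, "DEGENERATE_TEST_TRUTH")
  expect_null(parsed$auc)
})
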