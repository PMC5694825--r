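sim_features <- function(n, p_noise = 5, signal = TRUE, seed = 1) {
  withr::with_seed(seed, {
    outcome <- factor(rep(c("impaired", "unimpaired"), length.out = n),
                      levels = c("unimpaired", "impaired"))
    x <- as.data.frame(matrix(rnorm(n * p_noise), n, p_noise))
    names(x) <- paste0("noise", seq_len(p_noise))
    if (signal) x$signal <- as.numeric(outcome == "impaired") + rnorm(n, 0, 0.1)
    out <- tibble::as_tibble(cbind(
      tibble::tibble(subject_id = sprintf("s%04d", seq_len(n))), x,
      tibble::tibble(outcome = outcome)))
    attr(out, "feature_cols") <- setdiff(names(out),
                                         c("subject_id", "outcome"))
    out
  })
}

test_that("a duplicated outcome feature drives OOB error to zero", {
  fm <- sim_features(200, signal = TRUE, seed = 3)
  fit <- train_forest(fm, seed = 7)
  expect_lte(fit$oob_error, 0.05)
  expect_gt(fit$importances[["signal"]], max(
    fit$importances[paste0("noise", 1:5)]))
})

test_that("pure-noise features give chance-level OOB error", {
  errs <- vapply(1:20, function(s) {
    train_forest(sim_features(200, signal = FALSE, seed = s),
                 seed = s)$oob_error
  }, numeric(1))
  expect_true(all(errs >= 0.35 & errs <= 0.65))
})

test_that("training is deterministic given data and seed", {
  fm <- sim_features(80, seed = 5)
  f1 <- train_forest(fm, seed = 11)
  f2 <- train_forest(fm, seed = 11)
  expect_identical(f1$oob_error, f2$oob_error)
  expect_identical(f1$importances, f2$importances)
  expect_error(train_forest(dplyr::mutate(fm, outcome = factor("impaired"))),
               class = "cc_model_error")
})

test_that("exact binomial p-values match exhaustive enumeration", {
  for (n in 1:12) {
    for (k in 0:n) {
      pmf <- dbinom(0:n, n, 0.5)
      expected <- sum(pmf[pmf <= pmf[k + 1] + 1e-12])
      expect_equal(exact_binomial_test(k, n), expected,
                   tolerance = 1e-12)
    }
  }
  expect_equal(exact_binomial_test(8, 8), 0.0078125)
  expect_error(exact_binomial_test(3, 0), class = "cc_config_error")
})

test_that("hold-out evaluation reports the printed-style statistics", {
  fm <- sim_features(120, seed = 9)
  sp <- stratified_split(fm, seed = 2)
  train <- fm[match(sp$train_ids, fm$subject_id), ]
  test <- fm[match(sp$test_ids, fm$subject_id), ]
  attr(train, "feature_cols") <- attr(fm, "feature_cols")
  attr(test, "feature_cols") <- attr(fm, "feature_cols")
  fit <- train_forest(train, seed = 3)
  ev <- evaluate_holdout(fit, test)
  expect_equal(ev$n_test, length(sp$test_ids))
  expect_gte(ev$accuracy, 0.9)  # perfectly informative feature
  expect_equal(ev$auc, 1)
  expect_equal(ev$binomial_p,
               exact_binomial_test(round(ev$accuracy * ev$n_test), ev$n_test))
  expect_true(all(c("accuracy", "auc") %in% names(glance(ev))))
  expect_identical(tidy(ev)$feature[1], "signal")
})

test_that("the AUC follows the midrank convention and matches pROC", {
  skip_if_not_installed("pROC")
  withr::with_seed(8, {
    for (i in 1:5) {
      scores <- round(runif(40), 2)  # coarse scores force ties
      labels <- rbinom(40, 1, 0.5) == 1
      if (!any(labels) || all(labels)) next
      ours <- connectocast:::auc_score(scores, labels)
      ref <- suppressMessages(as.numeric(pROC::auc(
        pROC::roc(response = labels, predictor = scores,
                  direction = "<", quiet = TRUE))))
      expect_equal(ours, ref, tolerance = 1e-12)
    }
  })
})

test_that("OOB error agrees with an independent forest implementation", {
  skip_if_not_installed("randomForest")
  fm <- sim_features(150, signal = TRUE, seed = 13)
  ours <- train_forest(fm, seed = 1)
  xy <- connectocast:::forest_xy(fm)
  ref <- withr::with_seed(1, randomForest::randomForest(
    xy$x, xy$y, ntree = 500))
  ref_err <- unname(ref$err.rate[500, "OOB"])
  expect_lt(abs(ours$oob_error - ref_err), 0.05)
})

test_that("single-class test sets yield a warning and missing AUC", {
  fm <- sim_features(60, seed = 21)
  fit <- train_forest(fm, seed = 2)
  test1 <- fm[fm$outcome == "impaired", ][1:5, ]
  attr(test1, "feature_cols") <- attr(fm, "feature_cols")
  expect_warning(ev <- evaluate_holdout(fit, test1), regexp = "AUC")
  expect_true(is.na(ev$auc))
  expect_true(is.na(ev$specificity))
})
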