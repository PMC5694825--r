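#' Random-forest regression of individual cognitive test z-scores
#'
#' Fits one regression forest per cognitive test, predicting the 1-year
#' z-score from the supplied brain features. Model fit is reported as
#' adjusted R-squared computed from out-of-bag predictions:
#' `R2 = 1 - MSE_oob / Var(y)`, `adjR2 = 1 - (1 - R2)(n - 1)/(n - p - 1)`,
#' with a p-value from the F statistic implied by R2, n and p. Feature
#' importance is the percent increase in out-of-bag MSE under per-feature
#' permutation.
#'
#' @param features Tibble with `subject_id` and numeric feature columns
#'   (e.g. selected regions' clustering coefficients).
#' @param zscores Long tibble with `subject_id`, `test`, `z` for the target
#'   timepoint (one row per subject x test).
#' @param n_trees Trees per forest (default 500).
#' @param seed Integer seed (per-test substreams).
#' @return Object of class `cc_regression`: list with `results` (tibble of
#'   test, r_squared, adj_r_squared, f_statistic, p_value, n, p) and
#'   `importances` (tibble of test, feature, pct_inc_mse).
#' @export
rf_regress <- function(features, zscores, n_trees = 500, seed = 1L) {
  cols <- setdiff(names(features), "subject_id")
  if (length(cols) < 1) {
    abort("Need at least one feature.", class = "cc_config_error")
  }
  p <- length(cols)
  tests <- unique(zscores$test)
  res <- vector("list", length(tests))
  imp <- vector("list", length(tests))
  for (ti in seq_along(tests)) {
    dat <- zscores |>
      filter(.data$test == tests[ti]) |>
      select("subject_id", "z") |>
      dplyr::inner_join(features, by = "subject_id")
    dat <- dat[complete.cases(dat), , drop = FALSE]
    n <- nrow(dat)
    if (n - p - 1 <= 0) {
      abort(sprintf("Adjusted R^2 undefined for test %s: n - p - 1 <= 0.",
                    tests[ti]),
            class = "cc_config_error")
    }
    y <- dat$z
    if (stats::sd(y) < 1e-12) {
      abort(sprintf("Constant target for test %s.", tests[ti]),
            class = "cc_model_error")
    }
    fit <- ranger::ranger(
      dependent.variable.name = ".z",
      data = data.frame(dat[cols], .z = y, check.names = FALSE),
      num.trees = n_trees, mtry = max(1L, floor(p / 3)),
      importance = "permutation", num.threads = 1,
      seed = substream_seed(seed, 7L, ti)
    )
    mse <- unname(fit$prediction.error)
    var_y <- mean((y - mean(y))^2)
    r2 <- 1 - mse / var_y
    adj <- 1 - (1 - r2) * (n - 1) / (n - p - 1)
    fstat <- if (r2 >= 1) Inf else (r2 / p) / ((1 - r2) / (n - p - 1))
    pval <- if (r2 <= 0) 1 else pf(fstat, p, n - p - 1, lower.tail = FALSE)
    res[[ti]] <- tibble(test = tests[ti], r_squared = r2,
                        adj_r_squared = adj, f_statistic = fstat,
                        p_value = pval, n = n, p = p)
    imp[[ti]] <- tibble(test = tests[ti], feature = names(fit$variable.importance),
                        pct_inc_mse = 100 * unname(fit$variable.importance) / mse)
  }
  structure(list(results = bind_rows(res), importances = bind_rows(imp)),
            class = "cc_regression")
}

#' @export
print.cc_regression <- function(x, ...) {
  cat("<cc_regression>\n")
  print(x$results)
  invisible(x)
}
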