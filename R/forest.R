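#' Train a random-forest classifier with out-of-bag error estimation
#'
#' Grows an ensemble of CART trees on bootstrap samples, trying
#' `floor(sqrt(p))` randomly drawn features at each split, and reports the
#' out-of-bag misclassification error and mean-decrease-in-Gini feature
#' importances. Deterministic for a given seed.
#'
#' @param features A `cc_features` tibble, or a plain tibble/data frame of
#'   predictors when `outcome` is supplied separately.
#' @param outcome Optional factor outcome (taken from the `outcome` column
#'   when absent); the second level is the positive class.
#' @param n_trees Number of trees (default 500).
#' @param mtry Features tried per split; default `floor(sqrt(p))`.
#' @param seed Integer seed.
#' @return Object of class `cc_forest`: list with the fitted engine,
#'   `oob_error`, `importances` (named, mean decrease in Gini), `n_trees`,
#'   `mtry` and `feature_cols`.
#' @export
train_forest <- function(features, outcome = NULL, n_trees = 500,
                         mtry = NULL, seed = 1L) {
  xy <- forest_xy(features, outcome)
  if (nlevels(droplevels(xy$y)) < 2) {
    abort("Outcome is constant: cannot train a classifier.",
          class = "cc_model_error")
  }
  p <- ncol(xy$x)
  mtry <- mtry %||% max(1L, floor(sqrt(p)))
  dat <- data.frame(xy$x, .outcome = xy$y, check.names = FALSE)
  fit <- ranger::ranger(
    dependent.variable.name = ".outcome", data = dat,
    num.trees = n_trees, mtry = min(mtry, p),
    importance = "impurity", num.threads = 1, seed = seed,
    respect.unordered.factors = TRUE
  )
  structure(
    list(fit = fit, oob_error = unname(fit$prediction.error),
         importances = fit$variable.importance,
         n_trees = n_trees, mtry = min(mtry, p),
         feature_cols = colnames(xy$x), classes = levels(xy$y),
         positive = levels(xy$y)[2], seed = seed),
    class = "cc_forest"
  )
}

forest_xy <- function(features, outcome = NULL) {
  if (is.null(outcome)) {
    if (!"outcome" %in% names(features)) {
      abort("Provide `outcome` or an `outcome` column.",
            class = "cc_config_error")
    }
    outcome <- features$outcome
  }
  cols <- attr(features, "feature_cols") %||%
    setdiff(names(features), c("subject_id", "outcome"))
  x <- as.data.frame(features)[, cols, drop = FALSE]
  if (anyNA(x) || anyNA(outcome)) {
    abort("Missing values in features or outcome.", class = "cc_config_error")
  }
  list(x = x, y = as.factor(outcome),
       ids = features$subject_id %||% as.character(seq_len(nrow(x))))
}

#' @export
print.cc_forest <- function(x, ...) {
  cat(sprintf("<cc_forest> %d trees, mtry %d, %d features; OOB error %.3f\n",
              x$n_trees, x$mtry, length(x$feature_cols), x$oob_error))
  invisible(x)
}

# Fraction of trees voting for the positive class, per row of newdata.
forest_votes <- function(model, newdata) {
  x <- as.data.frame(newdata)[, model$feature_cols, drop = FALSE]
  pr <- predict(model$fit, data = x, predict.all = TRUE, num.threads = 1)
  pos_id <- match(model$positive, model$classes)
  rowMeans(pr$predictions == pos_id)
}

#' Predict classes with a trained forest
#'
#' @param object A `cc_forest`.
#' @param newdata Data with the model's feature columns.
#' @param type `"class"` (majority vote) or `"vote"` (positive-class vote
#'   fraction).
#' @param ... Unused.
#' @return Factor of predicted classes or numeric vote fractions.
#' @export
predict.cc_forest <- function(object, newdata, type = c("class", "vote"),
                              ...) {
  type <- match.arg(type)
  votes <- forest_votes(object, newdata)
  if (type == "vote") return(votes)
  factor(ifelse(votes > 0.5, object$positive,
                setdiff(object$classes, object$positive)),
         levels = object$classes)
}

#' Two-sided exact binomial test
#'
#' Exact two-sided p-value for `k` successes in `n` trials against success
#' probability `p0`, summing the probabilities of all outcomes no more
#' likely than the observed one (the minimum-likelihood convention).
#'
#' @param k Successes. @param n Trials. @param p0 Null success probability.
#' @return Two-sided p-value.
#' @export
#' @examples
#' exact_binomial_test(8, 8)  # 0.0078125
exact_binomial_test <- function(k, n, p0 = 0.5) {
  if (n < 1 || k < 0 || k > n) {
    abort("Need 0 <= k <= n with n >= 1.", class = "cc_config_error")
  }
  binom.test(k, n, p = p0)$p.value
}

# Mann-Whitney (midrank) AUC of scores against binary labels.
auc_score <- function(scores, positive) {
  pos <- as.logical(positive)
  n1 <- sum(pos)
  n0 <- sum(!pos)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(scores)
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Evaluate a trained forest on a held-out test set
#'
#' Computes accuracy, sensitivity (impaired as the positive class),
#' specificity, ROC AUC from the forest's vote fractions (midrank
#' convention under ties), and a two-sided exact binomial p-value of the
#' accuracy against chance 0.5.
#'
#' @param model A `cc_forest`.
#' @param test A `cc_features` tibble of held-out subjects (with `outcome`).
#' @return Object of class `cc_evaluation`: accuracy, sensitivity,
#'   specificity, auc, binomial_p, oob_error, importances, n_test, plus the
#'   per-subject `scores`, `labels` and `predicted` used downstream.
#' @export
evaluate_holdout <- function(model, test) {
  xy <- forest_xy(test)
  y <- factor(as.character(xy$y), levels = model$classes)
  votes <- forest_votes(model, xy$x)
  pred <- factor(ifelse(votes > 0.5, model$positive,
                        setdiff(model$classes, model$positive)),
                 levels = model$classes)
  pos <- y == model$positive
  correct <- pred == y
  acc <- mean(correct)
  sens <- if (any(pos)) mean(correct[pos]) else NA_real_
  spec <- if (any(!pos)) mean(correct[!pos]) else NA_real_
  auc <- auc_score(votes, pos)
  if (is.na(auc)) {
    rlang::warn("Single-class test set: AUC undefined, reported as NA.")
  }
  structure(
    list(accuracy = acc, sensitivity = sens, specificity = spec, auc = auc,
         binomial_p = exact_binomial_test(sum(correct), length(correct)),
         oob_error = model$oob_error, importances = model$importances,
         n_test = length(correct), scores = votes, labels = pos,
         predicted = pred, subject_ids = xy$ids),
    class = "cc_evaluation"
  )
}

#' @export
print.cc_evaluation <- function(x, ...) {
  cat(sprintf(paste0(
    "<cc_evaluation> n_test = %d\n",
    "  accuracy %.2f (exact binomial p = %.3f), AUC %s\n",
    "  sensitivity %s, specificity %s, OOB error %.3f\n"),
    x$n_test, x$accuracy, x$binomial_p,
    ifelse(is.na(x$auc), "NA", sprintf("%.2f", x$auc)),
    ifelse(is.na(x$sensitivity), "NA", sprintf("%.2f", x$sensitivity)),
    ifelse(is.na(x$specificity), "NA", sprintf("%.2f", x$specificity)),
    x$oob_error))
  invisible(x)
}
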