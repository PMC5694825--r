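#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a hold-out model evaluation
#'
#' `tidy()` returns one row per feature with its mean-decrease-in-Gini
#' importance; `glance()` returns a one-row summary of the evaluation.
#'
#' @param x A `cc_evaluation`.
#' @param ... Unused.
#' @return A tibble.
#' @method tidy cc_evaluation
#' @export
tidy.cc_evaluation <- function(x, ...) {
  tibble(feature = names(x$importances),
         gini_importance = unname(x$importances)) |>
    arrange(dplyr::desc(.data$gini_importance))
}

#' @rdname tidy.cc_evaluation
#' @method glance cc_evaluation
#' @export
glance.cc_evaluation <- function(x, ...) {
  tibble(accuracy = x$accuracy, sensitivity = x$sensitivity,
         specificity = x$specificity, auc = x$auc,
         binomial_p = x$binomial_p, oob_error = x$oob_error,
         n_test = x$n_test)
}

#' Tidy a recursive-feature-elimination result
#'
#' `tidy()` returns the accuracy profile over candidate subset sizes;
#' `glance()` the winning size and its mean inner accuracy.
#'
#' @param x A `cc_rfe`.
#' @param ... Unused.
#' @return A tibble.
#' @method tidy cc_rfe
#' @export
tidy.cc_rfe <- function(x, ...) x$profile

#' @rdname tidy.cc_rfe
#' @method glance cc_rfe
#' @export
glance.cc_rfe <- function(x, ...) {
  tibble(best_size = x$best_size,
         best_mean_accuracy = x$profile$mean_accuracy[
           x$profile$size == x$best_size],
         n_partitions = x$n_partitions)
}

#' Tidy a random-forest regression evaluation
#'
#' `tidy()` returns the per-feature percent increase in OOB MSE for every
#' test; `glance()` the per-test adjusted R-squared summary.
#'
#' @param x A `cc_regression`.
#' @param ... Unused.
#' @return A tibble.
#' @method tidy cc_regression
#' @export
tidy.cc_regression <- function(x, ...) x$importances

#' @rdname tidy.cc_regression
#' @method glance cc_regression
#' @export
glance.cc_regression <- function(x, ...) x$results
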