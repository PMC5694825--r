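#' Compare two models' AUCs by paired bootstrap
#'
#' Both evaluations must score the same held-out subjects. Test subjects are
#' resampled with replacement `n_bootstrap` times; both AUCs are recomputed
#' on each resample and the observed AUC difference is standardized by the
#' bootstrap standard deviation of the difference:
#' `z = (AUC1 - AUC2) / SD_boot(dAUC)`, with a two-sided normal p-value
#' (the Hanley-McNeil correlated-AUC comparison, bootstrap flavor).
#'
#' @param eval1,eval2 `cc_evaluation` objects on the same subjects.
#' @param n_bootstrap Number of bootstrap resamples (default 2000).
#' @param seed Integer seed.
#' @return Object of class `cc_auc_comparison`: one-row tibble with `auc1`,
#'   `auc2`, `delta`, `z`, `p_value`, `n_bootstrap`.
#' @export
compare_aucs <- function(eval1, eval2, n_bootstrap = 2000, seed = 1L) {
  if (length(eval1$labels) != length(eval2$labels) ||
      !all(eval1$labels == eval2$labels)) {
    abort("Evaluations must score the same subjects in the same order.",
          class = "cc_config_error")
  }
  labels <- eval1$labels
  if (sum(labels) < 2 || sum(!labels) < 2) {
    abort("Need at least 2 subjects per class to compare AUCs.",
          class = "cc_config_error")
  }
  n <- length(labels)
  auc1 <- auc_score(eval1$scores, labels)
  auc2 <- auc_score(eval2$scores, labels)
  deltas <- with_seed(seed, {
    vapply(seq_len(n_bootstrap), function(b) {
      repeat {
        idx <- sample.int(n, n, replace = TRUE)
        if (any(labels[idx]) && any(!labels[idx])) break
      }
      auc_score(eval1$scores[idx], labels[idx]) -
        auc_score(eval2$scores[idx], labels[idx])
    }, numeric(1))
  })
  sd_d <- stats::sd(deltas)
  delta <- auc1 - auc2
  z <- if (sd_d < 1e-12) {
    if (abs(delta) < 1e-12) 0 else sign(delta) * Inf
  } else {
    delta / sd_d
  }
  p <- if (is.infinite(z)) 0 else 2 * pnorm(-abs(z))
  structure(
    tibble(auc1 = auc1, auc2 = auc2, delta = delta, z = z,
           p_value = min(p, 1), n_bootstrap = n_bootstrap),
    class = c("cc_auc_comparison", class(tibble())))
}
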