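#' Recursive feature elimination by nested random-forest cross-validation
#'
#' Runs importance-ranked backward elimination on the training set. For each
#' of `n_partitions` seeded random stratified splits of the training set
#' into an inner training part A and inner testing part B, features are
#' ranked by mean decrease in Gini from a forest grown on A, and each
#' candidate subset size on a fixed ladder is scored by predicting the
#' held-out B samples (each B sample is predicted by a forest it never
#' trained; leave-one-out within the partition). The subset size with the
#' best mean accuracy across partitions wins (ties broken toward fewer
#' features); the selected features are the top-ranked features of that size
#' from a forest refit on the full training set.
#'
#' The ladder covers every size `p, p-1, ..., 1` for `p <= 20` and a
#' geometric (halving) ladder for larger `p`, keeping 96-feature models
#' tractable.
#'
#' @param train A `cc_features` tibble (training subjects only).
#' @param n_partitions Number of inner A/B partitions (default 100).
#' @param inner_fraction Fraction of the training set entering A (default
#'   0.75).
#' @param n_trees,mtry Forest parameters passed to [train_forest()].
#' @param seed Integer seed; expands to per-partition substreams.
#' @return Object of class `cc_rfe`: `selected_features` (ordered),
#'   `best_size`, `profile` (tibble of size and mean accuracy),
#'   `partition_accuracy` (size x partition matrix) and `final_ranking`.
#' @export
rfe_select <- function(train, n_partitions = 100, inner_fraction = 0.75,
                       n_trees = 500, mtry = NULL, seed = 1L) {
  if (n_partitions < 1) {
    abort("`n_partitions` must be >= 1.", class = "cc_config_error")
  }
  xy <- forest_xy(train)
  p <- ncol(xy$x)
  if (p < 1) abort("Need at least one feature.", class = "cc_config_error")
  ladder <- size_ladder(p)
  acc <- matrix(NA_real_, nrow = length(ladder), ncol = n_partitions,
                dimnames = list(paste0("size_", ladder), NULL))
  feats <- tibble(subject_id = xy$ids, outcome = xy$y)
  for (b in seq_len(n_partitions)) {
    part_seed <- substream_seed(seed, 101L, b)
    sp <- stratified_split(feats, fraction = inner_fraction, seed = part_seed)
    a_idx <- match(sp$train_ids, xy$ids)
    b_idx <- match(sp$test_ids, xy$ids)
    if (length(b_idx) == 0 || length(unique(xy$y[a_idx])) < 2) next
    xa <- xy$x[a_idx, , drop = FALSE]
    ya <- xy$y[a_idx]
    xb <- xy$x[b_idx, , drop = FALSE]
    yb <- xy$y[b_idx]
    full <- fit_rf(xa, ya, n_trees, mtry, substream_seed(part_seed, 1L))
    ranking <- names(sort(full$variable.importance, decreasing = TRUE))
    for (si in seq_along(ladder)) {
      k <- ladder[si]
      if (k == p) {
        pred <- predict(full, data = xb, num.threads = 1)$predictions
      } else {
        keep <- ranking[seq_len(k)]
        sub <- fit_rf(xa[, keep, drop = FALSE], ya, n_trees, mtry,
                      substream_seed(part_seed, 2L, si))
        pred <- predict(sub, data = xb[, keep, drop = FALSE],
                        num.threads = 1)$predictions
      }
      acc[si, b] <- mean(pred == yb)
    }
  }
  mean_acc <- rowMeans(acc, na.rm = TRUE)
  best_size <- ladder[which(mean_acc >= max(mean_acc) - 1e-12)]
  best_size <- min(best_size) # ties -> fewer features
  final <- fit_rf(xy$x, xy$y, n_trees, mtry, substream_seed(seed, 999L))
  final_ranking <- names(sort(final$variable.importance, decreasing = TRUE))
  structure(
    list(selected_features = final_ranking[seq_len(best_size)],
         best_size = best_size,
         profile = tibble(size = ladder, mean_accuracy = unname(mean_acc)),
         partition_accuracy = acc, final_ranking = final_ranking,
         n_partitions = n_partitions, seed = seed),
    class = "cc_rfe"
  )
}

size_ladder <- function(p) {
  if (p <= 20) return(seq(p, 1))
  sizes <- p
  while (sizes[length(sizes)] > 1) {
    sizes <- c(sizes, max(1, sizes[length(sizes)] %/% 2))
  }
  unique(sizes)
}

fit_rf <- function(x, y, n_trees, mtry, seed) {
  p <- ncol(x)
  ranger::ranger(
    dependent.variable.name = ".outcome",
    data = data.frame(x, .outcome = y, check.names = FALSE),
    num.trees = n_trees, mtry = min(mtry %||% max(1L, floor(sqrt(p))), p),
    importance = "impurity", num.threads = 1, seed = seed
  )
}

#' @export
print.cc_rfe <- function(x, ...) {
  cat(sprintf("<cc_rfe> best size %d of ladder [%s]; %d partitions\n",
              x$best_size, paste(x$profile$size, collapse = ", "),
              x$n_partitions))
  cat("  selected:", paste(x$selected_features, collapse = ", "), "\n")
  invisible(x)
}
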