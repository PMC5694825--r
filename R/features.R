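#' Assemble the per-patient feature matrix for one prediction model
#'
#' Model 1 uses the six baseline patient/medical covariates (age, education,
#' cancer stage at diagnosis, minority status, menopausal status, CAD
#' total). Model 2 adds baseline clustering coefficients of the three
#' a-priori regions ([model2_regions()]); Model 3 adds clustering
#' coefficients of all regions. Stage is encoded ordinally (I/II/III ->
#' 1/2/3), binaries as 0/1; clustering columns are named `cc_<region>`.
#'
#' @param metrics Long tibble of per-subject nodal metrics with columns
#'   `subject_id`, `region`, `clustering` (baseline).
#' @param covariates Tibble with `subject_id`, `age`, `education`, `stage`,
#'   `minority`, `menopause`, `cad`.
#' @param impairment Tibble with `subject_id` and `outcome_label`
#'   (`"impaired"`/`"unimpaired"`), e.g. from [classify_impairment()].
#' @param model `"model1"`, `"model2"` or `"model3"`.
#' @param regions Regions whose clustering enters Model 2 (default
#'   [model2_regions()]); ignored for the other models.
#' @return Object of class `cc_features`: tibble with `subject_id`, feature
#'   columns and an `outcome` factor (levels unimpaired < impaired), plus a
#'   `feature_cols` attribute.
#' @export
assemble_features <- function(metrics, covariates, impairment,
                              model = c("model1", "model2", "model3"),
                              regions = model2_regions()) {
  model <- match.arg(model)
  base <- covariates |>
    select("subject_id", "age", "education", "stage", "minority",
           "menopause", "cad") |>
    mutate(stage = as.numeric(match(.data$stage, c("I", "II", "III"))),
           minority = as.numeric(.data$minority),
           menopause = as.numeric(.data$menopause))
  if (any(is.na(base$stage))) {
    abort("`stage` must take values I, II or III.", class = "cc_config_error")
  }
  if (model != "model1") {
    wanted <- if (model == "model2") regions else unique(metrics$region)
    have <- unique(metrics$region)
    missing_regions <- setdiff(wanted, have)
    if (length(missing_regions) > 0) {
      abort(paste0("Region(s) absent from the metric table: ",
                   paste(missing_regions, collapse = ", ")),
            class = "cc_missing_region_error")
    }
    cc_wide <- metrics |>
      filter(.data$region %in% wanted) |>
      select("subject_id", "region", "clustering") |>
      tidyr::pivot_wider(names_from = "region", values_from = "clustering",
                         names_prefix = "cc_")
    base <- left_join(base, cc_wide, by = "subject_id")
  }
  out <- impairment |>
    select("subject_id", "outcome_label") |>
    dplyr::inner_join(base, by = "subject_id") |>
    mutate(outcome = factor(.data$outcome_label,
                            levels = c("unimpaired", "impaired"))) |>
    select(-"outcome_label")
  feature_cols <- setdiff(names(out), c("subject_id", "outcome"))
  if (anyNA(out[feature_cols])) {
    abort("Feature matrix contains missing values after assembly.",
          class = "cc_config_error")
  }
  structure(out, feature_cols = feature_cols,
            class = c("cc_features", class(out)))
}

#' Stratified train/test split of a feature matrix
#'
#' Samples the training fraction within each outcome class. Fractional
#' per-class test counts are rounded to the nearest integer, with exact
#' half counts resolved by a fair coin, so a 31-patient cohort with 17/14
#' classes yields a held-out set of 7 or 8.
#'
#' @param features A `cc_features` tibble (or any tibble with `subject_id`
#'   and `outcome`).
#' @param fraction Training fraction (default 0.75).
#' @param seed Integer seed.
#' @return Object of class `cc_split`: list with `train_ids`, `test_ids`,
#'   `fraction`, `seed`.
#' @export
stratified_split <- function(features, fraction = 0.75, seed = 1L) {
  if (fraction <= 0 || fraction >= 1) {
    abort("`fraction` must lie strictly between 0 and 1.",
          class = "cc_config_error")
  }
  cls <- split(features$subject_id, features$outcome, drop = FALSE)
  if (any(lengths(cls) == 0)) {
    abort("Both outcome classes must be present for a stratified split.",
          class = "cc_split_error")
  }
  res <- with_seed(seed, {
    test_ids <- character(0)
    for (ids in cls) {
      target <- (1 - fraction) * length(ids)
      n_test <- if (abs(target - floor(target) - 0.5) < 1e-9) {
        floor(target) + rbinom(1, 1, 0.5)
      } else {
        round(target)
      }
      n_test <- min(max(n_test, 0), length(ids) - 1)
      test_ids <- c(test_ids, sample(ids, n_test))
    }
    test_ids
  })
  structure(
    list(train_ids = setdiff(features$subject_id, res), test_ids = res,
         fraction = fraction, seed = seed),
    class = "cc_split"
  )
}

#' @export
print.cc_split <- function(x, ...) {
  cat(sprintf("<cc_split> %d train / %d test (fraction %.2f, seed %d)\n",
              length(x$train_ids), length(x$test_ids), x$fraction, x$seed))
  invisible(x)
}
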