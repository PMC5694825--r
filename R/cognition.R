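#' Default cognitive test battery and score directions
#'
#' Five standardized tests: RAVLT trial A1 (verbal learning) and A6 (verbal
#' retention), CTMT trails 1 and 5 (attention / processing speed /
#' executive function, timed so lower raw scores are better), and COWA
#' (verbal fluency). The direction flag makes negative z always mean worse
#' performance regardless of the raw scale.
#'
#' @return Tibble with columns `test` and `direction`
#'   (`"higher_better"` / `"lower_better"`).
#' @export
test_directions <- function() {
  tibble(
    test = c("RAVLT_A1", "RAVLT_A6", "CTMT_1", "CTMT_5", "COWA"),
    direction = c("higher_better", "higher_better", "lower_better",
                  "lower_better", "higher_better")
  )
}

#' Convert raw cognitive scores to control-referenced z-scores
#'
#' Each raw score is normalized against the control group's mean and
#' standard deviation for that test: `z = (raw - mean) / sd` for
#' higher-better tests and `z = -(raw - mean) / sd` for timed (lower-better)
#' tests, so negative z uniformly means worse-than-control performance.
#'
#' @param cognition Long tibble with columns `subject_id`, `group`,
#'   `timepoint`, `test`, `raw_score`.
#' @param control_group Value of `group` identifying controls (default
#'   `"control"`).
#' @param match_timepoint If `TRUE` (default) the control reference is
#'   computed per test and timepoint; if `FALSE`, baseline control data
#'   normalize all timepoints.
#' @param directions Tibble mapping `test` to `direction`; defaults to
#'   [test_directions()] with any unlisted test treated as higher-better.
#' @return Object of class `cc_zscores`: the input tibble with a `z` column,
#'   plus a `reference` attribute (control mean/sd per test and reference
#'   timepoint).
#' @export
compute_zscores <- function(cognition, control_group = "control",
                            match_timepoint = TRUE,
                            directions = test_directions()) {
  needed <- c("subject_id", "group", "timepoint", "test", "raw_score")
  missing_cols <- setdiff(needed, names(cognition))
  if (length(missing_cols) > 0) {
    abort(paste0("`cognition` lacks columns: ",
                 paste(missing_cols, collapse = ", ")),
          class = "cc_config_error")
  }
  controls <- filter(cognition, .data$group == control_group)
  if (nrow(controls) == 0) {
    abort(sprintf("No rows with group == \"%s\" to normalize against.",
                  control_group),
          class = "cc_config_error")
  }
  ref_keys <- if (match_timepoint) c("test", "timepoint") else "test"
  if (!match_timepoint) {
    controls <- filter(controls, .data$timepoint == "baseline")
  }
  reference <- controls |>
    group_by(across(all_of(ref_keys))) |>
    summarise(control_mean = mean(.data$raw_score, na.rm = TRUE),
              control_sd = stats::sd(.data$raw_score, na.rm = TRUE),
              n_controls = sum(!is.na(.data$raw_score)),
              .groups = "drop")
  bad <- filter(reference, .data$n_controls < 2 | !is.finite(.data$control_sd) |
                  .data$control_sd <= 0)
  if (nrow(bad) > 0) {
    abort(paste0("Control reference degenerate (sd <= 0 or n < 2) for test(s): ",
                 paste(unique(bad$test), collapse = ", ")),
          class = "cc_reference_error")
  }
  out <- cognition |>
    left_join(reference, by = ref_keys) |>
    left_join(directions, by = "test") |>
    mutate(
      direction = dplyr::coalesce(.data$direction, "higher_better"),
      z = (.data$raw_score - .data$control_mean) / .data$control_sd,
      z = ifelse(.data$direction == "lower_better", -.data$z, .data$z)
    ) |>
    select(all_of(needed), "z")
  structure(out, reference = reference, class = c("cc_zscores", class(out)))
}

#' Apply the ICCTF impairment rule to one timepoint's z-scores
#'
#' Performance at a timepoint is impaired when at least two z-scores are
#' -1.5 or lower, or at least one z-score is -2.0 or lower (thresholds
#' inclusive). Missing scores are ignored; all-missing input is an error.
#'
#' @param z Numeric vector of z-scores (typically 5, one per test).
#' @return Logical flag: impaired or not.
#' @export
#' @examples
#' classify_timepoint(c(-1.5, -1.5, 0, 0, 0))  # TRUE
#' classify_timepoint(c(-1.9, -1.4, 0, 0, 0))  # FALSE
classify_timepoint <- function(z) {
  z <- z[!is.na(z)]
  if (length(z) == 0) {
    abort("All z-scores missing: impairment undeterminable.",
          class = "cc_classification_error")
  }
  sum(z <= -1.5) >= 2 || any(z <= -2.0)
}

#' Longitudinal impairment outcome from baseline and 1-year status
#'
#' Impaired at both timepoints is persistent impairment; impaired only at
#' 1 year is late-onset impairment; both map to an impaired outcome.
#' Unimpaired at 1 year is an unimpaired outcome even when the baseline was
#' impaired (a resolved deficit falls outside both impairment categories;
#' such cases are flagged).
#'
#' @param impaired_baseline,impaired_year1 Logical flags per subject.
#' @return Tibble with columns `impaired_at_baseline`, `impaired_at_year1`,
#'   `outcome_label` (`"impaired"`/`"unimpaired"`), `category`
#'   (`"persistent"`, `"late_onset"`, `"none"`) and `resolved`.
#' @export
classify_longitudinal <- function(impaired_baseline, impaired_year1) {
  if (any(is.na(impaired_baseline)) || any(is.na(impaired_year1))) {
    abort("Both timepoints must be classified (no missing flags).",
          class = "cc_classification_error")
  }
  category <- dplyr::case_when(
    impaired_baseline & impaired_year1 ~ "persistent",
    !impaired_baseline & impaired_year1 ~ "late_onset",
    TRUE ~ "none"
  )
  tibble(
    impaired_at_baseline = impaired_baseline,
    impaired_at_year1 = impaired_year1,
    outcome_label = ifelse(category == "none", "unimpaired", "impaired"),
    category = category,
    resolved = impaired_baseline & !impaired_year1
  )
}

#' Classify every subject's longitudinal impairment status
#'
#' Applies [classify_timepoint()] at baseline and 1-year follow-up and
#' combines the flags with [classify_longitudinal()].
#'
#' @param zscores A `cc_zscores` tibble (or any long tibble with
#'   `subject_id`, `group`, `timepoint`, `test`, `z`).
#' @param baseline,year1 Timepoint labels (defaults `"baseline"`, `"year1"`).
#' @return Tibble with one row per subject: `subject_id`, `group`, the
#'   [classify_longitudinal()] columns and `n_tests_baseline` /
#'   `n_tests_year1` completeness counts.
#' @export
classify_impairment <- function(zscores, baseline = "baseline",
                                year1 = "year1") {
  tp <- zscores |>
    filter(.data$timepoint %in% c(baseline, year1)) |>
    group_by(.data$subject_id, .data$group, .data$timepoint) |>
    summarise(impaired = classify_timepoint(.data$z),
              n_tests = sum(!is.na(.data$z)), .groups = "drop") |>
    tidyr::pivot_wider(names_from = "timepoint",
                       values_from = c("impaired", "n_tests"))
  bcol <- paste0("impaired_", baseline)
  ycol <- paste0("impaired_", year1)
  if (!all(c(bcol, ycol) %in% names(tp)) ||
      any(is.na(tp[[bcol]])) || any(is.na(tp[[ycol]]))) {
    abort("Every subject needs classified baseline and 1-year timepoints.",
          class = "cc_classification_error")
  }
  dplyr::bind_cols(
    tp[, c("subject_id", "group")],
    classify_longitudinal(tp[[bcol]], tp[[ycol]]),
    tibble(n_tests_baseline = tp[[paste0("n_tests_", baseline)]],
           n_tests_year1 = tp[[paste0("n_tests_", year1)]])
  )
}

#' Two-sample test for equality of impairment proportions
#'
#' Pearson chi-squared test on the 2x2 incidence table, df = 1, two-sided,
#' without continuity correction by default (the convention matching the
#' uncorrected textbook statistic); Yates correction is available behind
#' `correct = TRUE`.
#'
#' @param k1,n1 Impaired count and group size, group 1.
#' @param k2,n2 Impaired count and group size, group 2.
#' @param correct Apply Yates continuity correction (default `FALSE`).
#' @return One-row tibble: `prop1`, `prop2`, `statistic` (X-squared), `df`,
#'   `p_value`, `correct`.
#' @export
#' @examples
#' incidence_proportion_test(17, 31, 11, 43)  # X^2 = 6.56, p = 0.010
incidence_proportion_test <- function(k1, n1, k2, n2, correct = FALSE) {
  if (n1 <= 0 || n2 <= 0 || k1 < 0 || k2 < 0 || k1 > n1 || k2 > n2) {
    abort("Counts must satisfy 0 <= k <= n with n > 0.",
          class = "cc_config_error")
  }
  if ((k1 + k2) == 0 || (k1 + k2) == (n1 + n2)) {
    abort("Chi-squared statistic undefined: an impairment margin is empty.",
          class = "cc_degenerate_error")
  }
  ht <- suppressWarnings(
    prop.test(c(k1, k2), c(n1, n2), correct = correct)
  )
  tibble(
    prop1 = k1 / n1, prop2 = k2 / n2,
    statistic = unname(ht$statistic), df = unname(ht$parameter),
    p_value = ht$p.value, correct = correct
  )
}
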