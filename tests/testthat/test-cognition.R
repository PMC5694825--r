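test_that("z-scores are control-referenced with direction handling", {
  cog <- tibble::tibble(
    subject_id = c(paste0("c", 1:4), "p1", "p1", "p1"),
    group = c(rep("control", 4), rep("patient", 3)),
    timepoint = "baseline",
    test = c(rep("RAVLT_A1", 4), "RAVLT_A1", "RAVLT_A1", "CTMT_1"),
    raw_score = c(8, 10, 12, 10, 10, 14, NA)
  )
  # control mean 10, sd = sqrt(8/3)
  cog$raw_score[7] <- 50
  ctmt <- tibble::tibble(subject_id = paste0("c", 1:4), group = "control",
                         timepoint = "baseline", test = "CTMT_1",
                         raw_score = c(40, 50, 60, 50))
  z <- compute_zscores(dplyr::bind_rows(cog, ctmt))
  sda <- sd(c(8, 10, 12, 10))
  expect_equal(z$z[z$subject_id == "p1" & z$test == "RAVLT_A1"],
               c(0, 4 / sda))
  # timed test: raw above control mean means slower, hence negative z
  sdc <- sd(c(40, 50, 60, 50))
  expect_equal(z$z[z$subject_id == "p1" & z$test == "CTMT_1"], 0)
  expect_equal(z$z[z$subject_id == "c1" & z$test == "CTMT_1"], 10 / sdc)
})

test_that("controls z-scored against themselves have mean 0 and sd 1", {
  cog <- cognition_panel(list(), n_controls = 15, seed = 5)
  z <- compute_zscores(cog)
  stats <- dplyr::summarise(
    dplyr::group_by(z, test, timepoint),
    m = mean(z), s = sd(z), .groups = "drop")
  expect_equal(stats$m, rep(0, nrow(stats)), tolerance = 1e-9)
  expect_equal(stats$s, rep(1, nrow(stats)), tolerance = 1e-9)
})

test_that("zero control variance is an explicit error naming the test", {
  cog <- tibble::tibble(subject_id = paste0("c", 1:3), group = "control",
                        timepoint = "baseline", test = "COWA",
                        raw_score = c(40, 40, 40))
  expect_error(compute_zscores(cog), regexp = "COWA",
               class = "cc_reference_error")
})

test_that("the impairment rule is inclusive at both thresholds", {
  expect_true(classify_timepoint(c(-1.5, -1.5, 0, 0, 0)))
  expect_true(classify_timepoint(c(-2.0, 0, 0, 0, 0)))
  expect_false(classify_timepoint(c(-1.9, -1.4, 0, 0, 0)))
  expect_false(classify_timepoint(c(-1.49, -1.49, -1.49, -1.49, -1.49)))
  expect_true(classify_timepoint(c(-2.01, 1, 1, 1, 1)))
  expect_error(classify_timepoint(c(NA, NA, NA, NA, NA)),
               class = "cc_classification_error")
  expect_true(classify_timepoint(c(NA, -2.0, NA, NA, NA)))
})

test_that("lowering a z-score can only move toward impairment", {
  withr::with_seed(99, {
    for (i in 1:1000) {
      z <- runif(5, -3, 1)
      before <- classify_timepoint(z)
      j <- sample(5, 1)
      z[j] <- z[j] - runif(1, 0, 2)
      after <- classify_timepoint(z)
      if (before) expect_true(after)
    }
  })
})

test_that("longitudinal categories follow the two-case impaired definition", {
  st <- classify_longitudinal(c(TRUE, FALSE, FALSE, TRUE),
                              c(TRUE, TRUE, FALSE, FALSE))
  expect_identical(st$category,
                   c("persistent", "late_onset", "none", "none"))
  expect_identical(st$outcome_label,
                   c("impaired", "impaired", "unimpaired", "unimpaired"))
  expect_identical(st$resolved, c(FALSE, FALSE, FALSE, TRUE))
  expect_error(classify_longitudinal(NA, TRUE),
               class = "cc_classification_error")
})

test_that("per-subject classification aggregates timepoints correctly", {
  # deviations chosen far from the rule thresholds so sampling noise in the
  # control reference cannot flip the classification
  panel <- list(
    p1 = list(baseline = c(-2.6, -2.7, 0, 0, 0),
              year1 = c(-3.2, 0, 0, 0, 0)),      # persistent
    p2 = list(baseline = c(0.5, 0.2, 0, 0.3, 0),
              year1 = c(-2.5, -2.5, 0, 0, 0)),   # late onset
    p3 = list(baseline = c(-3.5, 0, 0, 0, 0),
              year1 = c(0.4, 0, 0.2, 0, 0))      # resolved -> unimpaired
  )
  cog <- cognition_panel(panel, n_controls = 400, seed = 8)
  z <- compute_zscores(cog)
  st <- classify_impairment(z)
  pats <- st[st$group == "patient", ]
  expect_identical(pats$category[match(c("p1", "p2", "p3"),
                                       pats$subject_id)],
                   c("persistent", "late_onset", "none"))
})

test_that("incidence test reproduces the uncorrected chi-squared", {
  res <- incidence_proportion_test(17, 31, 11, 43)
  expect_equal(round(res$statistic, 2), 6.56)
  expect_equal(round(res$p_value, 3), 0.010)
  # Yates-corrected variant, hand-computed from the 2x2 table
  yates <- incidence_proportion_test(17, 31, 11, 43, correct = TRUE)
  o <- c(17, 14, 11, 32)
  n <- 74
  e <- c(28 * 31, 46 * 31, 28 * 43, 46 * 43) / n
  x2_hand <- sum((abs(o - e) - 0.5)^2 / e)
  expect_equal(yates$statistic, x2_hand)
  expect_lt(yates$statistic, res$statistic)
})

test_that("chi-squared equals the textbook formula and is symmetric", {
  for (k1 in seq(5, 45, 10)) {
    for (k2 in seq(0, 50, 10)) {
      n1 <- 50; n2 <- 50
      if ((k1 + k2) %in% c(0, n1 + n2)) next
      res <- incidence_proportion_test(k1, n1, k2, n2)
      o <- c(k1, n1 - k1, k2, n2 - k2)
      rowt <- c(k1 + k2, n1 + n2 - k1 - k2)
      e <- c(rowt[1] * n1, rowt[2] * n1, rowt[1] * n2, rowt[2] * n2) /
        (n1 + n2)
      expect_equal(res$statistic, sum((o - e)^2 / e))
      swapped <- incidence_proportion_test(k2, n2, k1, n1)
      expect_equal(res$statistic, swapped$statistic)
    }
  }
})

test_that("equal proportions give a zero statistic and degenerate margins error", {
  res <- incidence_proportion_test(10, 20, 10, 20)
  expect_equal(res$statistic, 0)
  expect_equal(res$p_value, 1)
  expect_error(incidence_proportion_test(0, 20, 0, 30),
               class = "cc_degenerate_error")
  expect_error(incidence_proportion_test(20, 20, 30, 30),
               class = "cc_degenerate_error")
})
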