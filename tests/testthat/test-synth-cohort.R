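small_config <- function(...) {
  cohort_config(n_patients = 20, n_controls = 12, n_regions = 30,
                n_modules = 3, predictive_regions = c(4, 12, 25), seed = 5,
                ...)
}

test_that("configuration invariants are enforced", {
  expect_error(cohort_config(impairment_rate_patients = 1.2),
               class = "cc_config_error")
  expect_error(cohort_config(within_module_weight_mean = 0.2,
                             between_module_weight_mean = 0.4),
               class = "cc_config_error")
  expect_error(cohort_config(n_regions = 10, n_modules = 20),
               class = "cc_config_error")
  expect_error(cohort_config(n_regions = 30, predictive_regions = c(2, 31)),
               class = "cc_config_error")
  expect_error(cohort_config(predictive_regions = "No_Such_Region"),
               class = "cc_config_error")
  expect_error(cohort_config(cognitive_effect_sd_units = -1),
               class = "cc_config_error")
})

test_that("identical config and seed reproduce the cohort byte for byte", {
  c1 <- simulate_cohort(small_config())
  c2 <- simulate_cohort(small_config())
  expect_identical(serialize(c1, NULL), serialize(c2, NULL))
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_cohort(c1, d1)
  write_cohort(c2, d2)
  f1 <- list.files(d1, recursive = TRUE)
  expect_identical(f1, list.files(d2, recursive = TRUE))
  for (f in f1) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
  }
})

test_that("subject substreams are stable under cohort growth", {
  small <- simulate_cohort(small_config())
  grown <- simulate_cohort(cohort_config(
    n_patients = 26, n_controls = 14, n_regions = 30, n_modules = 3,
    predictive_regions = c(4, 12, 25), seed = 5))
  shared <- small$subjects$subject_id
  expect_identical(small$subjects,
                   grown$subjects[match(shared, grown$subjects$subject_id), ])
  expect_identical(small$matrices$baseline[["p003"]],
                   grown$matrices$baseline[["p003"]])
})

test_that("every matrix is symmetric with zero diagonal in [-1, 1]", {
  coh <- simulate_cohort(small_config())
  for (m in coh$matrices$baseline) {
    expect_identical(m, t(m))
    expect_equal(unname(diag(m)), rep(0, nrow(m)))
    expect_true(all(m >= -1 & m <= 1))
  }
})

test_that("matrix files round-trip through the delimited format", {
  coh <- simulate_cohort(small_config())
  dir <- withr::local_tempdir()
  write_cohort(coh, dir)
  m <- read_connectivity_matrix(
    file.path(dir, "matrices", "baseline", "p001.csv"))
  expect_equal(m, coh$matrices$baseline$p001)
})

test_that("a single module makes all edges within-module draws", {
  cfg1 <- cohort_config(n_patients = 4, n_controls = 2, n_regions = 24,
                        n_modules = 1, predictive_regions = c(3, 9),
                        clustering_effect = 0, seed = 9)
  coh <- simulate_cohort(cfg1)
  w <- coh$matrices$baseline[[1]]
  offdiag <- w[upper.tri(w)]
  # all edges from the within-module distribution: mean near the within mean
  expect_equal(mean(offdiag), cfg1$within_module_weight_mean,
               tolerance = 0.02)
  # and no between-module dip anywhere: sd near the configured dispersion
  expect_equal(sd(offdiag), cfg1$weight_sd, tolerance = 0.02)
})

test_that("zero clustering effect leaves groups statistically exchangeable", {
  # mean clustering of predictive regions: impaired vs unimpaired patients,
  # expected non-significant in nearly all seeds
  pvals <- vapply(1:50, function(s) {
    cfg <- cohort_config(n_patients = 30, n_controls = 8, n_regions = 30,
                         n_modules = 3, predictive_regions = c(4, 12, 25),
                         clustering_effect = 0, seed = s)
    coh <- simulate_cohort(cfg)
    pats <- coh$subjects[coh$subjects$group == "patient", ]
    nets <- binarize_cohort(coh$matrices$baseline[pats$subject_id])
    cc <- vapply(nets, function(nw) {
      mean(clustering_coefficient(nw)[cfg$predictive_idx])
    }, numeric(1))
    imp <- pats$true_outcome == "impaired"
    if (sum(imp) < 3 || sum(!imp) < 3) return(1)
    t.test(cc[imp], cc[!imp])$p.value
  }, numeric(1))
  expect_gte(sum(pvals > 0.01), 45)
})

test_that("a planted clustering effect lowers impaired patients' clustering", {
  cfg <- cohort_config(n_patients = 200, n_controls = 8, n_regions = 30,
                       n_modules = 3, predictive_regions = c(4, 12, 25),
                       clustering_effect = 0.5, seed = 21)
  coh <- simulate_cohort(cfg)
  pats <- coh$subjects[coh$subjects$group == "patient", ]
  nets <- binarize_cohort(coh$matrices$baseline[pats$subject_id])
  cc <- vapply(nets, function(nw) {
    mean(clustering_coefficient(nw)[cfg$predictive_idx])
  }, numeric(1))
  imp <- pats$true_outcome == "impaired"
  expect_lt(mean(cc[imp]), mean(cc[!imp]))
})

test_that("expected planted-region clustering is non-increasing in effect", {
  mean_cc <- vapply(c(0, 0.25, 0.5), function(eff) {
    cfg <- cohort_config(n_patients = 100, n_controls = 8, n_regions = 30,
                         n_modules = 3, predictive_regions = c(4, 12, 25),
                         clustering_effect = eff, seed = 77)
    coh <- simulate_cohort(cfg)
    pats <- coh$subjects[coh$subjects$group == "patient", ]
    imp_ids <- pats$subject_id[pats$true_outcome == "impaired"]
    nets <- binarize_cohort(coh$matrices$baseline[pats$subject_id])
    mean(vapply(nets[imp_ids], function(nw) {
      mean(clustering_coefficient(nw)[cfg$predictive_idx])
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(mean_cc) <= 0))
})

test_that("realized impairment rates track their targets", {
  rates <- vapply(1:10, function(s) {
    coh <- simulate_cohort(cohort_config(n_patients = 100, n_controls = 60,
                                         seed = s),
                           timepoints = character(0))
    z <- compute_zscores(coh$cognition)
    st <- classify_impairment(z)
    mean(st$outcome_label[st$group == "patient"] == "impaired")
  }, numeric(1))
  expect_lt(abs(mean(rates) - 0.55), 0.10)
})

test_that("classified rate stays near target at scale (3 SD effect)", {
  coh <- simulate_cohort(cohort_config(n_patients = 1000, n_controls = 200,
                                       impairment_rate_patients = 0.55,
                                       cognitive_effect_sd_units = 3,
                                       seed = 3),
                         timepoints = character(0))
  st <- classify_impairment(compute_zscores(coh$cognition))
  rate <- mean(st$outcome_label[st$group == "patient"] == "impaired")
  expect_gte(rate, 0.45)
  expect_lte(rate, 0.65)
})

test_that("zero cognitive effect equalizes patient and control rates", {
  coh <- simulate_cohort(cohort_config(n_patients = 400, n_controls = 400,
                                       cognitive_effect_sd_units = 0,
                                       seed = 17),
                         timepoints = character(0))
  st <- classify_impairment(compute_zscores(coh$cognition))
  k <- table(st$group, st$outcome_label)
  p <- incidence_proportion_test(k["patient", "impaired"], 400,
                                 k["control", "impaired"], 400)
  expect_gt(p$p_value, 0.01)
})

test_that("pure late-onset cohorts have no planted baseline impairment", {
  cfg <- cohort_config(n_patients = 150, n_controls = 150,
                       late_onset_fraction = 1, seed = 13)
  coh <- simulate_cohort(cfg, timepoints = character(0))
  st <- classify_impairment(compute_zscores(coh$cognition))
  # with every planted deficit late-onset, baseline impairment is only the
  # rule's base rate; compare against a persistent-heavy cohort
  cfg0 <- cohort_config(n_patients = 150, n_controls = 150,
                        late_onset_fraction = 0, seed = 13)
  st0 <- classify_impairment(compute_zscores(
    simulate_cohort(cfg0, timepoints = character(0))$cognition))
  base_late <- mean(st$impaired_at_baseline[st$group == "patient"])
  base_pers <- mean(st0$impaired_at_baseline[st0$group == "patient"])
  expect_lt(base_late, base_pers - 0.15)
  expect_identical(
    unique(st$category[st$group == "patient" &
                         st$outcome_label == "impaired" &
                         !st$impaired_at_baseline]),
    "late_onset")
})

test_that("covariates are outcome-neutral by default and responsive to weights", {
  coh <- simulate_cohort(cohort_config(n_patients = 500, n_controls = 500,
                                       seed = 19), timepoints = character(0))
  pats <- coh$subjects[coh$subjects$group == "patient", ]
  r <- cor(pats$age, as.numeric(pats$true_outcome == "impaired"))
  expect_lt(abs(r), 0.1)
  cohw <- simulate_cohort(cohort_config(
    n_patients = 500, n_controls = 10, seed = 19,
    covariate_weights = c(age = 1.5)), timepoints = character(0))
  pw <- cohw$subjects[cohw$subjects$group == "patient", ]
  expect_gt(mean(pw$age[pw$planted]), mean(pw$age[!pw$planted]))
  expect_error(
    simulate_cohort(cohort_config(covariate_weights = c(bogus = 1))),
    class = "cc_config_error")
})

test_that("stage probabilities produce the configured mixture", {
  coh <- simulate_cohort(cohort_config(n_patients = 300, n_controls = 10,
                                       seed = 23), timepoints = character(0))
  stage_freq <- prop.table(table(coh$subjects$stage))
  expect_equal(as.numeric(stage_freq[c("I", "II", "III")]),
               c(0.16, 0.65, 0.19), tolerance = 0.08)
})
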