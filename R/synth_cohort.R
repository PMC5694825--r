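#' Configuration for a synthetic connectome-and-cognition cohort
#'
#' Defines the generative conditions for a seeded synthetic cohort: modular
#' weighted connectivity matrices with a planted clustering deficit in
#' designated regions for to-be-impaired patients, cognition trajectories on
#' which the ICCTF rule recovers the configured impairment rates, and
#' outcome-neutral covariates. Defaults mirror the study population the
#' pipeline was built around: 31 patients vs 43 controls, 90 regions in 5
#' modules, 55% patient / 26% control impairment with 41% of impaired
#' patients late-onset.
#'
#' @param n_patients,n_controls Group sizes.
#' @param n_regions Number of regions (default 90).
#' @param n_modules Number of network modules (default 5).
#' @param within_module_weight_mean,between_module_weight_mean Mean edge
#'   weight (correlation scale) inside vs between modules; within must
#'   exceed between.
#' @param weight_sd Edge-weight dispersion around the block mean.
#' @param predictive_regions Regions carrying the planted deficit: region
#'   labels (see [region_labels()]) or 1-based indices. Default: the five
#'   regions of [default_predictive_regions()].
#' @param clustering_effect Fractional down-weighting of edges among each
#'   predictive region's strongest neighbors in impaired patients, in
#'   `[0, 1]`; 0 disables the brain effect.
#' @param impairment_rate_patients,impairment_rate_controls Target realized
#'   impairment proportions.
#' @param late_onset_fraction Proportion of planted-impaired subjects whose
#'   deficit appears only at follow-up.
#' @param cognitive_effect_sd_units Downward shift of impaired subjects'
#'   scores, in control-SD units, applied to two tests.
#' @param covariate_weights Named log-odds weights tying covariates to the
#'   planting probability (names among age, education, stage, minority,
#'   menopause, cad); default all zero, i.e. covariates carry no outcome
#'   signal.
#' @param seed Integer master seed; expands to per-subject substreams so
#'   changing cohort size does not reshuffle existing subjects.
#' @return Object of class `cc_cohort_config` (validated list).
#' @export
cohort_config <- function(n_patients = 31, n_controls = 43, n_regions = 90,
                          n_modules = 5,
                          within_module_weight_mean = 0.6,
                          between_module_weight_mean = 0.2,
                          weight_sd = 0.15,
                          predictive_regions = default_predictive_regions(),
                          clustering_effect = 0.5,
                          impairment_rate_patients = 0.55,
                          impairment_rate_controls = 0.26,
                          late_onset_fraction = 0.41,
                          cognitive_effect_sd_units = 3,
                          covariate_weights = NULL,
                          seed = 1L) {
  cfg <- list(
    n_patients = check_count(n_patients, "n_patients"),
    n_controls = check_count(n_controls, "n_controls", min = 2),
    n_regions = check_count(n_regions, "n_regions", min = 3),
    n_modules = check_count(n_modules, "n_modules"),
    within_module_weight_mean = within_module_weight_mean,
    between_module_weight_mean = between_module_weight_mean,
    weight_sd = weight_sd,
    predictive_regions = predictive_regions,
    clustering_effect = clustering_effect,
    impairment_rate_patients = check_proportion(impairment_rate_patients,
                                                "impairment_rate_patients"),
    impairment_rate_controls = check_proportion(impairment_rate_controls,
                                                "impairment_rate_controls"),
    late_onset_fraction = check_proportion(late_onset_fraction,
                                           "late_onset_fraction"),
    cognitive_effect_sd_units = cognitive_effect_sd_units,
    covariate_weights = covariate_weights %||% numeric(0),
    seed = check_count(seed, "seed", min = 0)
  )
  if (cfg$n_modules > cfg$n_regions) {
    abort("`n_modules` cannot exceed `n_regions`.", class = "cc_config_error")
  }
  if (!(within_module_weight_mean > between_module_weight_mean)) {
    abort("`within_module_weight_mean` must exceed `between_module_weight_mean`.",
          class = "cc_config_error")
  }
  if (!is.numeric(clustering_effect) || clustering_effect < 0) {
    abort("`clustering_effect` must be >= 0.", class = "cc_config_error")
  }
  if (!is.numeric(cognitive_effect_sd_units) || cognitive_effect_sd_units < 0) {
    abort("`cognitive_effect_sd_units` must be >= 0.",
          class = "cc_config_error")
  }
  labs <- region_labels(cfg$n_regions)
  cfg$region_labels <- labs
  cfg$predictive_idx <- resolve_regions(predictive_regions, labs)
  cfg$module_of <- rep(seq_len(cfg$n_modules),
                       each = ceiling(cfg$n_regions / cfg$n_modules))[
                         seq_len(cfg$n_regions)]
  structure(cfg, class = "cc_cohort_config")
}

resolve_regions <- function(regions, labs) {
  if (is.character(regions)) {
    idx <- match(regions, labs)
    if (any(is.na(idx))) {
      abort(paste0("Unknown predictive region label(s): ",
                   paste(regions[is.na(idx)], collapse = ", ")),
            class = "cc_config_error")
    }
    idx
  } else {
    idx <- as.integer(regions)
    if (any(is.na(idx)) || any(idx < 1) || any(idx > length(labs))) {
      abort("Predictive region indices must lie in [1, n_regions].",
            class = "cc_config_error")
    }
    idx
  }
}

#' @export
print.cc_cohort_config <- function(x, ...) {
  cat(sprintf(paste0(
    "<cc_cohort_config> %d patients / %d controls, %d regions in %d modules\n",
    "  clustering_effect %.2f on %d regions; cognitive effect %.1f SD\n",
    "  target impairment: patients %.2f, controls %.2f (late-onset %.2f); seed %d\n"),
    x$n_patients, x$n_controls, x$n_regions, x$n_modules,
    x$clustering_effect, length(x$predictive_idx),
    x$cognitive_effect_sd_units, x$impairment_rate_patients,
    x$impairment_rate_controls, x$late_onset_fraction, x$seed))
  invisible(x)
}

# Reference raw-score distributions for the five tests. Raw scales are
# arbitrary by construction (z-scoring against controls makes them
# immaterial downstream); values are plausible for the instruments.
reference_tests <- function() {
  dplyr::inner_join(
    tibble(
      test = c("RAVLT_A1", "RAVLT_A6", "CTMT_1", "CTMT_5", "COWA"),
      ref_mean = c(7.5, 11, 45, 95, 40),
      ref_sd = c(2, 2.5, 12, 25, 11)
    ),
    test_directions(), by = "test"
  )
}

# Exact probability that a subject trips the ICCTF rule (>= 2 z-scores
# <= -1.5 or >= 1 z-score <= -2.0) at one timepoint, when `n_shifted` of
# the n_tests standard-normal latent scores are shifted down by `shift`
# and z-scores are taken against a control reference with latent mean
# `m_ref` and SD `s_ref`.
rule_trip_prob <- function(shift, m_ref = 0, s_ref = 1, n_tests = 5,
                           n_shifted = 2) {
  mu <- c(rep(shift, n_shifted), rep(0, n_tests - n_shifted))
  p2 <- pnorm(m_ref - 2 * s_ref + mu)     # P(z <= -2)
  p15 <- pnorm(m_ref - 1.5 * s_ref + mu)  # P(z <= -1.5)
  b <- p15 - p2                           # P(-2 < z <= -1.5)
  cc <- 1 - p15                           # P(z > -1.5)
  not_tripped <- prod(cc) + sum(vapply(seq_len(n_tests), function(i) {
    b[i] * prod(cc[-i])
  }, numeric(1)))
  1 - not_tripped
}

# Latent mean/SD of the control score distribution at a timepoint, given
# the control planting rate q: a planted control has 2 of 5 tests shifted
# down by `effect` (persistent from baseline, late-onset from follow-up),
# so each test is marginally shifted with probability pi.
control_reference <- function(q, effect, late_onset_fraction, timepoint) {
  shifted_frac <- if (timepoint == "baseline") 1 - late_onset_fraction else 1
  pi_t <- q * shifted_frac * 2 / 5
  list(m = -pi_t * effect, s = sqrt(1 + pi_t * (1 - pi_t) * effect^2))
}

# Calibrate planting probabilities so the ICCTF rate realized against the
# control group's own (mixture) reference hits the configured targets.
# The control rate is a fixed point (the reference moments depend on the
# control planting rate), solved by bisection; the patient probability then
# follows in closed form. All quantities are exact under the Gaussian
# score model.
calibrate_rates <- function(config) {
  eff <- config$cognitive_effect_sd_units
  # Planted control deficits are capped at the rule's severe-impairment
  # threshold (2 SD): control impairment is mild-to-moderate by definition,
  # and milder control deficits keep the control reference distribution
  # close to Gaussian, so sample-referenced z-scores downstream behave like
  # the population-referenced ones used here.
  eff_c <- min(eff, 2)
  late <- config$late_onset_fraction
  realized_control <- function(q) {
    ref <- control_reference(q, eff_c, late, "year1")
    q * rule_trip_prob(eff_c, ref$m, ref$s) +
      (1 - q) * rule_trip_prob(0, ref$m, ref$s)
  }
  # The realized control rate is non-monotone in the planting rate (planted
  # deficits inflate the control reference SD, which pushes the z thresholds
  # out), so the target may be reachable only approximately; take the
  # smallest planting rate whose realized rate is closest to the target.
  target_c <- config$impairment_rate_controls
  grid <- seq(0, 1, by = 0.0025)
  realized <- vapply(grid, realized_control, numeric(1))
  qc <- grid[which.min(abs(realized - target_c))]
  ref_b <- control_reference(qc, eff_c, late, "baseline")
  ref_y <- control_reference(qc, eff_c, late, "year1")
  fp <- rule_trip_prob(0, ref_y$m, ref_y$s)
  hit <- rule_trip_prob(eff, ref_y$m, ref_y$s)
  qp <- if (hit - fp < 1e-6) {
    config$impairment_rate_patients
  } else {
    min(max((config$impairment_rate_patients - fp) / (hit - fp), 0), 1)
  }
  list(q_patient = qp, q_control = qc, effect_patient = eff,
       effect_control = eff_c,
       reference = list(baseline = ref_b, post_chemo = ref_y, year1 = ref_y))
}

#' Generate one subject's covariate record
#'
#' Age uniform on 34-65 years, education in years, cancer stage I-III at the
#' study's stage distribution (16/65/19%), minority and post-menopausal
#' binaries, and a continuous CAD (psychological distress) total.
#'
#' @param config A [cohort_config()].
#' @param subject_seed Integer substream seed for this subject.
#' @return One-row tibble of covariates.
#' @export
generate_covariates <- function(config, subject_seed) {
  with_seed(subject_seed, tibble(
    age = runif(1, 34, 65),
    education = round(pmin(pmax(rnorm(1, 16.5, 2.6), 8), 22)),
    stage = sample(c("I", "II", "III"), 1, prob = c(0.16, 0.65, 0.19)),
    minority = rbinom(1, 1, 0.3),
    menopause = rbinom(1, 1, 0.35),
    cad = rnorm(1, 50, 10)
  ))
}

covariate_linear_predictor <- function(weights, cov) {
  if (length(weights) == 0) return(0)
  std <- c(
    age = (cov$age - 49.5) / 9,
    education = (cov$education - 16.5) / 2.6,
    stage = match(cov$stage, c("I", "II", "III")) - 2,
    minority = cov$minority - 0.3,
    menopause = cov$menopause - 0.35,
    cad = (cov$cad - 50) / 10
  )
  unknown <- setdiff(names(weights), names(std))
  if (length(unknown) > 0) {
    abort(paste0("Unknown covariate weight(s): ",
                 paste(unknown, collapse = ", ")),
          class = "cc_config_error")
  }
  sum(weights * std[names(weights)])
}

#' Generate one subject's raw cognition trajectories
#'
#' Controls (and unplanted patients) draw from the reference distributions
#' at all three timepoints. Planted-impaired subjects are shifted down by
#' `cognitive_effect_sd_units` control SDs on two randomly chosen tests at
#' the timepoints their category dictates: persistent at baseline,
#' post-chemotherapy and 1 year; late-onset from post-chemotherapy on. The
#' returned record carries the subject's realized outcome under the
#' population control reference.
#'
#' @param config A [cohort_config()].
#' @param subject_seed Integer substream seed.
#' @param planted Logical: does this subject carry the planted deficit?
#' @param planted_category `"persistent"` or `"late_onset"` (ignored when
#'   not planted).
#' @param group `"patient"` or `"control"`: planted control deficits are
#'   capped at 2 SD (mild-to-moderate impairment), patients carry the full
#'   configured effect.
#' @param calibration Precomputed calibration (internal use); derived from
#'   `config` when `NULL`.
#' @return List with `scores` (long tibble: timepoint, test, raw_score),
#'   `true_outcome` (`"impaired"`/`"unimpaired"`) and `true_category`.
#' @export
generate_cognition <- function(config, subject_seed, planted = FALSE,
                               planted_category = "persistent",
                               group = "patient", calibration = NULL) {
  calibration <- calibration %||% calibrate_rates(config)
  refs <- reference_tests()
  eff <- if (group == "control") calibration$effect_control
         else calibration$effect_patient
  timepoints <- c("baseline", "post_chemo", "year1")
  shift_at <- if (!planted) character(0)
              else if (planted_category == "late_onset") c("post_chemo", "year1")
              else timepoints
  res <- with_seed(subject_seed, {
    shifted_tests <- sample(refs$test, 2)
    scores <- tidyr::expand_grid(timepoint = timepoints, test = refs$test) |>
      left_join(refs, by = "test") |>
      mutate(
        eps = rnorm(dplyr::n()),
        shift_z = ifelse(.data$test %in% shifted_tests &
                           .data$timepoint %in% shift_at, eff, 0),
        # downward shift in performance: direction-aware on the raw scale
        raw_score = .data$ref_mean + .data$ref_sd *
          ifelse(.data$direction == "lower_better",
                 -(.data$eps - .data$shift_z),
                 .data$eps - .data$shift_z)
      )
    scores
  })
  # realized status against the population control (mixture) reference,
  # matching the sample-control normalization applied downstream
  imp <- vapply(timepoints, function(tp) {
    ref <- calibration$reference[[tp]]
    rows <- res$timepoint == tp
    zpop <- (res$eps[rows] - res$shift_z[rows] - ref$m) / ref$s
    classify_timepoint(zpop)
  }, logical(1))
  status <- classify_longitudinal(imp[["baseline"]], imp[["year1"]])
  list(
    scores = select(res, "timepoint", "test", "raw_score"),
    true_outcome = status$outcome_label,
    true_category = status$category
  )
}

#' Generate one subject's weighted connectivity matrix
#'
#' Block-structured Gaussian edge weights around the within/between module
#' means, clipped to `[-1, 1]`, symmetric with zero diagonal. For impaired
#' patients, edges among each predictive region's top-k strongest neighbors
#' (k near the expected binarized degree) are down-weighted by
#' `clustering_effect`, lowering that region's expected clustering
#' coefficient while approximately preserving its degree.
#'
#' @param config A [cohort_config()].
#' @param subject_seed Integer substream seed.
#' @param impaired Logical: apply the planted deficit?
#' @return Symmetric numeric matrix with region labels as dimnames.
#' @export
generate_connectivity <- function(config, subject_seed, impaired = FALSE) {
  n <- config$n_regions
  mod <- config$module_of
  mu <- matrix(config$between_module_weight_mean, n, n)
  same <- outer(mod, mod, `==`)
  mu[same] <- config$within_module_weight_mean
  with_seed(subject_seed, {
    w <- matrix(0, n, n)
    ut <- upper.tri(w)
    w[ut] <- rnorm(sum(ut), mean = mu[ut], sd = config$weight_sd)
    w <- w + t(w)
    if (impaired && config$clustering_effect > 0) {
      k <- max(4L, round(0.1 * (n - 1)))
      for (r in config$predictive_idx) {
        nb <- setdiff(order(w[r, ], decreasing = TRUE), r)[seq_len(k)]
        w[nb, nb] <- w[nb, nb] * (1 - config$clustering_effect)
      }
    }
    w <- pmin(pmax(w, -1), 1)
    diag(w) <- 0
    dimnames(w) <- list(config$region_labels, config$region_labels)
    w
  })
}

#' Simulate a full synthetic cohort
#'
#' Generates covariates, cognition trajectories and connectivity matrices
#' for every subject, expanding the master seed into per-subject substreams
#' (covariates, planting, cognition and each timepoint's matrix draw their
#' own streams). The same config and seed always reproduce the identical
#' cohort.
#'
#' @param config A [cohort_config()].
#' @param timepoints Timepoints at which to generate connectivity matrices
#'   (`"baseline"` by default; prediction consumes baseline only). Use
#'   `character(0)` to skip matrices entirely.
#' @return Object of class `cc_cohort`: list with `subjects` (tibble of id,
#'   group, covariates, planted flags, true outcome/category), `cognition`
#'   (long tibble), `matrices` (per timepoint, a named list of matrices) and
#'   `config`.
#' @export
simulate_cohort <- function(config, timepoints = "baseline") {
  stopifnot(inherits(config, "cc_cohort_config"))
  all_tp <- c("baseline", "post_chemo", "year1")
  if (!all(timepoints %in% all_tp)) {
    abort("`timepoints` must be among baseline, post_chemo, year1.",
          class = "cc_config_error")
  }
  groups <- c(rep("patient", config$n_patients),
              rep("control", config$n_controls))
  within_idx <- c(seq_len(config$n_patients), seq_len(config$n_controls))
  ids <- ifelse(groups == "patient",
                sprintf("p%03d", within_idx), sprintf("c%03d", within_idx))
  calibration <- calibrate_rates(config)
  q_base <- c(patient = calibration$q_patient,
              control = calibration$q_control)
  mats <- setNames(vector("list", length(timepoints)), timepoints)
  for (tp in timepoints) mats[[tp]] <- setNames(vector("list", length(ids)), ids)

  rows <- vector("list", length(ids))
  cog <- vector("list", length(ids))
  for (i in seq_along(ids)) {
    gcode <- if (groups[i] == "patient") 1L else 2L
    sseed <- function(stream) {
      substream_seed(config$seed, gcode, within_idx[i], stream)
    }
    cov <- generate_covariates(config, sseed(1L))
    q <- q_base[[groups[i]]]
    lp <- covariate_linear_predictor(config$covariate_weights, cov)
    if (lp != 0) {
      q <- plogis(qlogis(min(max(q, 1e-6), 1 - 1e-6)) + lp)
    }
    draws <- with_seed(sseed(2L), runif(2))
    planted <- draws[1] < q
    planted_category <- if (draws[2] < config$late_onset_fraction) {
      "late_onset"
    } else "persistent"
    cg <- generate_cognition(config, sseed(3L), planted, planted_category,
                             group = groups[i], calibration = calibration)
    impaired <- cg$true_outcome == "impaired"
    for (ti in seq_along(timepoints)) {
      tp <- timepoints[ti]
      mats[[tp]][[ids[i]]] <- generate_connectivity(
        config, sseed(10L + match(tp, all_tp)),
        impaired = impaired && groups[i] == "patient"
      )
    }
    rows[[i]] <- dplyr::bind_cols(
      tibble(subject_id = ids[i], group = groups[i]), cov,
      tibble(planted = planted,
             planted_category = ifelse(planted, planted_category, "none"),
             true_outcome = cg$true_outcome,
             true_category = cg$true_category)
    )
    cog[[i]] <- mutate(cg$scores, subject_id = ids[i], group = groups[i],
                       .before = 1)
  }
  structure(
    list(subjects = bind_rows(rows), cognition = bind_rows(cog),
         matrices = mats, config = config),
    class = "cc_cohort"
  )
}

#' @export
print.cc_cohort <- function(x, ...) {
  cat(sprintf(
    "<cc_cohort> %d patients / %d controls; matrices at: %s\n",
    sum(x$subjects$group == "patient"), sum(x$subjects$group == "control"),
    if (length(x$matrices)) paste(names(x$matrices), collapse = ", ") else "none"))
  cat(sprintf("  realized impairment: patients %.2f, controls %.2f\n",
              mean(x$subjects$true_outcome[x$subjects$group == "patient"] == "impaired"),
              mean(x$subjects$true_outcome[x$subjects$group == "control"] == "impaired")))
  invisible(x)
}

#' Write a synthetic cohort to delimited text files
#'
#' Writes one labeled square CSV matrix per subject per timepoint under
#' `matrices/<timepoint>/<subject_id>.csv`, plus `cognition.csv` (long
#' format), `covariates.csv` and `truth.csv` (hidden generator labels for
#' evaluation).
#'
#' @param cohort A `cc_cohort`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (tp in names(cohort$matrices)) {
    mdir <- file.path(dir, "matrices", tp)
    dir.create(mdir, recursive = TRUE, showWarnings = FALSE)
    for (id in names(cohort$matrices[[tp]])) {
      utils::write.csv(cohort$matrices[[tp]][[id]],
                       file.path(mdir, paste0(id, ".csv")))
    }
  }
  utils::write.csv(cohort$cognition, file.path(dir, "cognition.csv"),
                   row.names = FALSE)
  covs <- select(cohort$subjects, "subject_id", "group", "age", "education",
                 "stage", "minority", "menopause", "cad")
  utils::write.csv(covs, file.path(dir, "covariates.csv"), row.names = FALSE)
  truth <- select(cohort$subjects, "subject_id", "group", "planted",
                  "planted_category", "true_outcome", "true_category")
  utils::write.csv(truth, file.path(dir, "truth.csv"), row.names = FALSE)
  invisible(dir)
}

#' Read a labeled square connectivity matrix from CSV
#'
#' @param path CSV with region labels as header row and first column.
#' @return Numeric matrix with dimnames.
#' @export
read_connectivity_matrix <- function(path) {
  df <- utils::read.csv(path, row.names = 1, check.names = FALSE)
  m <- as.matrix(df)
  storage.mode(m) <- "double"
  check_connectivity_matrix(m)
}
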