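#' Pipeline run configuration
#'
#' Bundles everything [run_pipeline()] needs: where to write outputs, the
#' synthetic-cohort configuration (or a directory of existing input tables
#' and matrices laid out as [write_cohort()] writes them), which prediction
#' models to run, and the seeds/parameters of the stochastic stages. All
#' stage seeds are derived deterministically from `seed`.
#'
#' @param out_dir Output directory.
#' @param seed Master pipeline seed.
#' @param cohort A [cohort_config()] (used when `input_dir` is `NULL`).
#' @param input_dir Optional directory with `cognition.csv`,
#'   `covariates.csv` and `matrices/baseline/*.csv` to analyse instead of
#'   simulating.
#' @param models Character subset of `model1`/`model2`/`model3`.
#' @param density_mode Binarization mode for feature extraction
#'   (`"cohort_common"` or `"per_subject"`).
#' @param n_partitions Inner partitions for [rfe_select()].
#' @param n_trees Trees per forest.
#' @param n_bootstrap Bootstrap resamples for [compare_aucs()].
#' @param train_fraction Stratified training fraction.
#' @return Object of class `cc_pipeline_config`.
#' @export
pipeline_config <- function(out_dir, seed = 1L, cohort = cohort_config(),
                            input_dir = NULL,
                            models = c("model1", "model2", "model3"),
                            density_mode = c("cohort_common", "per_subject"),
                            n_partitions = 100, n_trees = 500,
                            n_bootstrap = 2000, train_fraction = 0.75) {
  models <- match.arg(models, several.ok = TRUE)
  structure(
    list(out_dir = out_dir, seed = check_count(seed, "seed", min = 0),
         cohort = cohort, input_dir = input_dir, models = models,
         density_mode = match.arg(density_mode),
         n_partitions = check_count(n_partitions, "n_partitions"),
         n_trees = check_count(n_trees, "n_trees"),
         n_bootstrap = check_count(n_bootstrap, "n_bootstrap"),
         train_fraction = train_fraction),
    class = "cc_pipeline_config"
  )
}

#' Read a pipeline configuration from a YAML file
#'
#' The file may contain any [pipeline_config()] field; a `cohort` block is
#' passed to [cohort_config()].
#'
#' @param path YAML file.
#' @param out_dir Optional override of the configured output directory.
#' @return A `cc_pipeline_config`.
#' @export
read_pipeline_config <- function(path, out_dir = NULL) {
  if (!file.exists(path)) {
    abort(sprintf("Config file does not exist: %s", path),
          class = "cc_config_error")
  }
  raw <- yaml::read_yaml(path)
  if (!is.null(raw$cohort)) raw$cohort <- do.call(cohort_config, raw$cohort)
  if (!is.null(out_dir)) raw$out_dir <- out_dir
  do.call(pipeline_config, raw)
}

# ---- stage machinery --------------------------------------------------------

config_signature <- function(x) {
  x <- x[sort(names(x))]
  json <- jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA, force = TRUE)
  tf <- tempfile()
  on.exit(unlink(tf))
  writeLines(as.character(json), tf)
  unname(tools::md5sum(tf))
}

hash_files <- function(paths) {
  paths <- sort(unlist(paths))
  h <- tools::md5sum(paths)
  setNames(unname(h), basename(names(h)))
}

# Run a stage unless its recorded input hashes + config signature still
# match and all outputs exist, in which case `load` replays the outputs.
stage_run <- function(state, name, inputs, signature, outputs, compute, load) {
  manifest_path <- file.path(state$out_dir, paste0(".stage_", name, ".json"))
  in_hash <- hash_files(inputs)
  fresh <- file.exists(manifest_path) && all(file.exists(outputs))
  if (fresh) {
    man <- jsonlite::read_json(manifest_path, simplifyVector = TRUE)
    fresh <- identical(man$signature, unname(signature)) &&
      identical(as.list(man$input_hashes), as.list(in_hash))
  }
  if (fresh) {
    value <- load()
    state$stages[[name]] <- "skipped"
  } else {
    t0 <- proc.time()[["elapsed"]]
    value <- compute()
    message(sprintf("[connectocast] stage %-8s ran in %.1fs", name,
                    proc.time()[["elapsed"]] - t0))
    jsonlite::write_json(
      list(stage = name, signature = unname(signature),
           input_hashes = as.list(hash_files(inputs))),
      manifest_path, auto_unbox = TRUE, digits = NA)
    state$stages[[name]] <- "ran"
  }
  value
}

evaluation_to_list <- function(ev, selected, rfe_profile = NULL) {
  list(
    accuracy = ev$accuracy, sensitivity = ev$sensitivity,
    specificity = ev$specificity, auc = ev$auc, binomial_p = ev$binomial_p,
    oob_error = ev$oob_error, n_test = ev$n_test,
    selected_features = selected,
    importances = as.list(ev$importances),
    scores = as.numeric(ev$scores), labels = as.logical(ev$labels),
    subject_ids = ev$subject_ids,
    rfe_profile = rfe_profile
  )
}

evaluation_from_list <- function(x) {
  structure(
    list(accuracy = x$accuracy, sensitivity = x$sensitivity,
         specificity = x$specificity, auc = x$auc, binomial_p = x$binomial_p,
         oob_error = x$oob_error,
         importances = unlist(x$importances), n_test = x$n_test,
         scores = as.numeric(x$scores), labels = as.logical(x$labels),
         predicted = NULL, subject_ids = x$subject_ids),
    class = "cc_evaluation"
  )
}

load_cohort_dir <- function(dir) {
  mat_dir <- file.path(dir, "matrices", "baseline")
  if (!dir.exists(mat_dir)) {
    abort(sprintf("Matrix directory does not exist: %s", mat_dir),
          class = "cc_input_error")
  }
  files <- list.files(mat_dir, pattern = "\\.csv$", full.names = TRUE)
  mats <- setNames(map(files, read_connectivity_matrix),
                   sub("\\.csv$", "", basename(files)))
  cognition <- as_tibble(utils::read.csv(file.path(dir, "cognition.csv")))
  covariates <- as_tibble(utils::read.csv(file.path(dir, "covariates.csv")))
  list(cognition = cognition, covariates = covariates,
       matrices = list(baseline = mats))
}

# ---- pipeline ---------------------------------------------------------------

#' Run the full prediction pipeline
#'
#' Orchestrates simulate (or load) -> impairment scoring -> descriptive
#' connectome metrics and hub characterization -> per-model nested-RFE
#' random-forest prediction -> AUC comparisons -> regression of individual
#' 1-year z-scores, writing every stage's outputs plus a consolidated JSON
#' report. Re-running with the same configuration and seed reproduces the
#' report byte for byte; stages whose inputs are unchanged on disk are
#' skipped.
#'
#' Held-out subjects never participate in feature selection, forest
#' training, or binarization-density selection: the cohort-common density
#' used for feature extraction is the maximum of the training patients'
#' minimum connection densities.
#'
#' @param config A [pipeline_config()] or path to a YAML file.
#' @return Object of class `cc_run`: list with `report` (the consolidated
#'   report), `stages` (named status vector: ran/skipped), `report_path`
#'   and `out_dir`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "cc_pipeline_config"))
  if (!is.null(config$input_dir) && !dir.exists(config$input_dir)) {
    abort(sprintf("Input directory does not exist: %s", config$input_dir),
          class = "cc_input_error")
  }
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  state <- new.env()
  state$out_dir <- out
  state$stages <- list()

  cohort_sig <- config_signature(list(
    cohort = unclass(config$cohort)[setdiff(names(config$cohort),
                                            c("region_labels", "module_of"))],
    input_dir = config$input_dir))

  # -- stage 1: simulate or load ------------------------------------------
  data_dir <- config$input_dir %||% file.path(out, "cohort")
  truth_path <- file.path(data_dir, "truth.csv")
  dat <- stage_run(
    state, "simulate", inputs = character(0), signature = cohort_sig,
    outputs = c(file.path(data_dir, c("cognition.csv", "covariates.csv")),
                file.path(data_dir, "matrices", "baseline")),
    compute = function() {
      if (is.null(config$input_dir)) {
        write_cohort(simulate_cohort(config$cohort), data_dir)
      }
      load_cohort_dir(data_dir)
    },
    load = function() load_cohort_dir(data_dir)
  )

  # -- stage 2: impairment scoring ----------------------------------------
  impair_sig <- config_signature(list(stage = "impair"))
  impair_inputs <- file.path(data_dir, "cognition.csv")
  zsc_path <- file.path(out, "zscores.csv")
  imp_path <- file.path(out, "impairment.csv")
  inc_path <- file.path(out, "incidence.json")
  impair <- stage_run(
    state, "impair", inputs = impair_inputs, signature = impair_sig,
    outputs = c(zsc_path, imp_path, inc_path),
    compute = function() {
      z <- compute_zscores(dat$cognition)
      status <- classify_impairment(z)
      utils::write.csv(z, zsc_path, row.names = FALSE)
      utils::write.csv(status, imp_path, row.names = FALSE)
      inc <- incidence_summary(status)
      jsonlite::write_json(inc, inc_path, auto_unbox = TRUE, digits = NA,
                           pretty = TRUE)
      list(zscores = as_tibble(z), status = status, incidence = inc)
    },
    load = function() {
      list(zscores = as_tibble(utils::read.csv(zsc_path)),
           status = as_tibble(utils::read.csv(imp_path)),
           incidence = jsonlite::read_json(inc_path, simplifyVector = TRUE))
    }
  )

  patients <- filter(impair$status, .data$group == "patient")
  pat_mats <- dat$matrices$baseline[patients$subject_id]
  if (any(vapply(pat_mats, is.null, logical(1)))) {
    abort("Missing baseline matrices for some patients.",
          class = "cc_input_error")
  }

  # -- stage 3: descriptive metrics + hubs (patient group) ----------------
  metrics_sig <- config_signature(list(stage = "metrics",
                                       density_mode = config$density_mode))
  nm_path <- file.path(out, "node_metrics.csv")
  hub_path <- file.path(out, "hubs.csv")
  part_path <- file.path(out, "partition.csv")
  metr <- stage_run(
    state, "metrics", inputs = impair_inputs, signature = metrics_sig,
    outputs = c(nm_path, hub_path, part_path),
    compute = function() {
      nets <- binarize_cohort(pat_mats, mode = config$density_mode)
      per_subject <- imap(nets, function(nw, id) {
        mutate(node_metrics(nw, partition = detect_modules(nw)),
               subject_id = id, .before = 1)
      }) |> bind_rows()
      gm <- group_mean_metrics(nets)
      hubs <- classify_hubs(gm$metrics)
      utils::write.csv(per_subject, nm_path, row.names = FALSE)
      utils::write.csv(hubs, hub_path, row.names = FALSE)
      utils::write.csv(
        tibble(region = names(gm$partition$membership),
               module = unname(gm$partition$membership)),
        part_path, row.names = FALSE)
      list(per_subject = per_subject, group = gm$metrics, hubs = hubs,
           modularity = gm$partition$modularity)
    },
    load = function() {
      hubs <- as_tibble(utils::read.csv(hub_path))
      list(per_subject = as_tibble(utils::read.csv(nm_path)),
           group = NULL, hubs = hubs, modularity = NULL)
    }
  )

  # -- stage 4: per-model prediction --------------------------------------
  predict_sig <- config_signature(list(
    stage = "predict", models = config$models, seed = config$seed,
    n_partitions = config$n_partitions, n_trees = config$n_trees,
    train_fraction = config$train_fraction,
    density_mode = config$density_mode))
  eval_paths <- setNames(
    file.path(out, paste0(sub("model", "model_", config$models),
                          "_evaluation.json")), config$models)
  feat_path <- file.path(out, "features_brain.csv")
  imps_path <- file.path(out, "importances.csv")
  pred <- stage_run(
    state, "predict", inputs = impair_inputs, signature = predict_sig,
    outputs = c(unname(eval_paths), feat_path, imps_path),
    compute = function() {
      split_seed <- substream_seed(config$seed, 301L)
      sp <- stratified_split(
        assemble_features(tibble(subject_id = character(0),
                                 region = character(0),
                                 clustering = numeric(0)),
                          dat$covariates, patients, model = "model1"),
        fraction = config$train_fraction, seed = split_seed)
      # density from training patients only, applied to everyone
      nets <- binarize_cohort(pat_mats, mode = config$density_mode,
                              density_reference_ids = sp$train_ids)
      cc_long <- imap(nets, function(nw, id) {
        tibble(subject_id = id, region = nw$region_labels,
               clustering = unname(clustering_coefficient(nw)))
      }) |> bind_rows()
      utils::write.csv(
        tidyr::pivot_wider(cc_long, names_from = "region",
                           values_from = "clustering"),
        feat_path, row.names = FALSE)
      evals <- list()
      imp_rows <- list()
      for (m in config$models) {
        fm <- assemble_features(cc_long, dat$covariates, patients, model = m)
        train <- fm[fm$subject_id %in% sp$train_ids, ]
        test <- fm[fm$subject_id %in% sp$test_ids, ]
        attr(train, "feature_cols") <- attr(fm, "feature_cols")
        attr(test, "feature_cols") <- attr(fm, "feature_cols")
        rfe <- rfe_select(train, n_partitions = config$n_partitions,
                          n_trees = config$n_trees,
                          seed = substream_seed(config$seed, 302L, m))
        sel_train <- train[, c("subject_id", rfe$selected_features,
                               "outcome")]
        attr(sel_train, "feature_cols") <- rfe$selected_features
        fit <- train_forest(sel_train, n_trees = config$n_trees,
                            seed = substream_seed(config$seed, 303L, m))
        ev <- evaluate_holdout(fit, test)
        evals[[m]] <- evaluation_to_list(
          ev, rfe$selected_features,
          rfe_profile = list(size = rfe$profile$size,
                             mean_accuracy = rfe$profile$mean_accuracy))
        jsonlite::write_json(evals[[m]], eval_paths[[m]], auto_unbox = TRUE,
                             digits = NA, pretty = TRUE)
        imp_rows[[m]] <- tibble(model = m, feature = names(ev$importances),
                                gini_importance = unname(ev$importances))
      }
      utils::write.csv(bind_rows(imp_rows), imps_path, row.names = FALSE)
      list(evals = evals, split = sp)
    },
    load = function() {
      list(evals = map(eval_paths, function(p) {
        jsonlite::read_json(p, simplifyVector = TRUE)
      }), split = NULL)
    }
  )

  # -- stage 5: AUC comparisons -------------------------------------------
  cmp_path <- file.path(out, "auc_comparisons.json")
  cmp_sig <- config_signature(list(stage = "compare", seed = config$seed,
                                   n_bootstrap = config$n_bootstrap))
  comparisons <- stage_run(
    state, "compare", inputs = unname(eval_paths), signature = cmp_sig,
    outputs = cmp_path,
    compute = function() {
      res <- list()
      if (length(config$models) >= 2) {
        prs <- utils::combn(config$models, 2, simplify = FALSE)
        for (pr in prs) {
          e1 <- evaluation_from_list(pred$evals[[pr[1]]])
          e2 <- evaluation_from_list(pred$evals[[pr[2]]])
          cmp <- compare_aucs(e1, e2, n_bootstrap = config$n_bootstrap,
                              seed = substream_seed(config$seed, 304L,
                                                    pr[1], pr[2]))
          res[[paste(pr, collapse = "_vs_")]] <-
            as.list(as.data.frame(cmp))
        }
      }
      jsonlite::write_json(res, cmp_path, auto_unbox = TRUE, digits = NA,
                           pretty = TRUE)
      res
    },
    load = function() jsonlite::read_json(cmp_path, simplifyVector = TRUE)
  )

  # -- stage 6: regression of year-1 z-scores -----------------------------
  reg_path <- file.path(out, "regression.json")
  reg_sig <- config_signature(list(stage = "regress", seed = config$seed,
                                   n_trees = config$n_trees,
                                   models = config$models))
  regression <- stage_run(
    state, "regress", inputs = unname(eval_paths), signature = reg_sig,
    outputs = reg_path,
    compute = function() {
      brain_model <- if ("model3" %in% config$models) "model3"
                     else if ("model2" %in% config$models) "model2"
                     else NULL
      if (is.null(brain_model)) {
        res <- list(note = "no brain-feature model run; regression skipped")
      } else {
        sel <- grep("^cc_", pred$evals[[brain_model]]$selected_features,
                    value = TRUE)
        if (length(sel) == 0) {
          res <- list(note = "no brain features selected; regression skipped")
        } else if (length(sel) + 1 >= nrow(patients)) {
          res <- list(note = paste(
            "adjusted R^2 undefined:", length(sel),
            "selected features for", nrow(patients),
            "patients; regression skipped"))
        } else {
          feats <- as_tibble(utils::read.csv(feat_path, check.names = FALSE))
          names(feats)[-1] <- paste0("cc_", names(feats)[-1])
          reg <- rf_regress(
            feats[feats$subject_id %in% patients$subject_id,
                  c("subject_id", sel)],
            filter(impair$zscores, .data$timepoint == "year1",
                   .data$subject_id %in% patients$subject_id),
            n_trees = config$n_trees,
            seed = substream_seed(config$seed, 305L))
          res <- list(features = sel,
                      results = as.list(reg$results),
                      importances = as.list(reg$importances))
        }
      }
      jsonlite::write_json(res, reg_path, auto_unbox = TRUE, digits = NA,
                           pretty = TRUE)
      res
    },
    load = function() jsonlite::read_json(reg_path, simplifyVector = TRUE)
  )

  # -- stage 7: consolidated report ---------------------------------------
  selected_regions <- unique(unlist(map(pred$evals, function(e) {
    sub("^cc_", "", grep("^cc_", e$selected_features, value = TRUE))
  })))
  hub_table <- filter(metr$hubs, .data$region %in% selected_regions)
  report <- list(
    software = list(package = "connectocast",
                    version = as.character(utils::packageVersion("connectocast"))),
    seed = config$seed,
    config_signatures = list(cohort = unname(cohort_sig),
                             predict = unname(predict_sig)),
    incidence = impair$incidence,
    models = map(pred$evals, function(e) {
      e[c("accuracy", "sensitivity", "specificity", "auc", "binomial_p",
          "oob_error", "n_test", "selected_features")]
    }),
    auc_comparisons = comparisons,
    hub_table = as.list(hub_table),
    regression = regression
  )
  report_path <- file.path(out, "report.json")
  jsonlite::write_json(report, report_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  structure(list(report = report, stages = unlist(state$stages),
                 report_path = report_path, out_dir = out),
            class = "cc_run")
}

incidence_summary <- function(status) {
  pat <- filter(status, .data$group == "patient")
  ctl <- filter(status, .data$group == "control")
  k1 <- sum(pat$outcome_label == "impaired")
  k2 <- sum(ctl$outcome_label == "impaired")
  test <- tryCatch(
    as.list(incidence_proportion_test(k1, nrow(pat), k2, nrow(ctl))),
    error = function(e) list(note = conditionMessage(e)))
  n_imp <- max(k1, 1L)
  list(
    patients = list(impaired = k1, n = nrow(pat), rate = k1 / nrow(pat)),
    controls = list(impaired = k2, n = nrow(ctl), rate = k2 / nrow(ctl)),
    persistent_fraction = sum(pat$category == "persistent") / n_imp,
    late_onset_fraction = sum(pat$category == "late_onset") / n_imp,
    test = test
  )
}

#' @export
print.cc_run <- function(x, ...) {
  cat("<cc_run> stages:",
      paste(sprintf("%s[%s]", names(x$stages), x$stages), collapse = " "),
      "\n  report:", x$report_path, "\n")
  invisible(x)
}
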