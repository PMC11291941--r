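#' Experiment configuration
#'
#' One configuration drives the full two-phase experiment: a model-building
#' phase (simulate cohort, fit the residual reserve criterion, split 75/25,
#' tune and fit a boosted surrogate per tier, evaluate held-out accuracy and
#' the fixed-parameter latent correlation) and an external-validation phase
#' (simulate a longitudinal cohort, predict surrogate scores, and run the
#' moderation ladder per tier plus education-only and word-reading-only
#' comparison ladders).
#'
#' @param seed Top-level seed, expanded deterministically into per-stage seeds.
#' @param building Generative config for the model-building cohort.
#' @param validation Generative config for the validation cohort.
#' @param tiers Character vector of tiers to train.
#' @param train_fraction Training fraction for the split.
#' @param tuner A [tuner_config()]; its seed is overridden per run.
#' @param comparison_ladders Run the education and word-reading comparison
#'   ladders.
#' @return List of class `experiment_config`.
#' @export
experiment_config <- function(seed = 1L,
                              building = generative_config(seed = seed),
                              validation = generative_config(
                                n_participants = 1640L, seed = seed + 1L),
                              tiers = c("minimal", "extended", "full"),
                              train_fraction = 0.75,
                              tuner = tuner_config(),
                              comparison_ladders = TRUE) {
  structure(list(seed = as.integer(seed), building = building,
                 validation = validation, tiers = tiers,
                 train_fraction = train_fraction, tuner = tuner,
                 comparison_ladders = comparison_ladders),
            class = "experiment_config")
}

#' Read an experiment configuration from YAML or JSON
#'
#' Scalar overrides in the file are merged over [experiment_config()] and
#' [generative_config()] defaults. Top-level keys mirror the
#' `experiment_config` arguments; `building` and `validation` are maps of
#' `generative_config` arguments; `tuner` a map of [tuner_config()] arguments.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return An `experiment_config`.
#' @export
read_experiment_config <- function(path) {
  raw <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else jsonlite::read_json(path, simplifyVector = TRUE)
  seed <- as.integer(raw$seed %||% 1L)
  build_args <- c(list(seed = seed), raw$building)
  build_args <- build_args[!duplicated(names(build_args), fromLast = TRUE)]
  val_args <- c(list(seed = seed + 1L, n_participants = 1640L), raw$validation)
  val_args <- val_args[!duplicated(names(val_args), fromLast = TRUE)]
  tuner_args <- raw$tuner %||% list()
  experiment_config(
    seed = seed,
    building = do.call(generative_config, lapply(build_args, unlist)),
    validation = do.call(generative_config, lapply(val_args, unlist)),
    tiers = raw$tiers %||% c("minimal", "extended", "full"),
    train_fraction = raw$train_fraction %||% 0.75,
    tuner = do.call(tuner_config, tuner_args),
    comparison_ladders = raw$comparison_ladders %||% TRUE)
}

#' Run the full two-phase experiment
#'
#' Executes, in order: model-building simulation, criterion fitting and
#' scoring, train/test split, per-tier hyperparameter tuning and final fits,
#' held-out evaluation, fixed-parameter latent correlations, validation-phase
#' simulation, per-tier surrogate prediction and moderation ladders (plus
#' education and word-reading comparison ladders), and attribution tables.
#' All tabular artifacts are written as CSV/JSON under `out_dir` together
#' with a run manifest of seeds and file checksums.
#'
#' @param config An [experiment_config()].
#' @param out_dir Output directory (created if needed); `NULL` skips writing.
#' @return Invisibly, a list of class `experiment_result` with elements
#'   `criterion_params`, `criterion_scores`, `tiers` (per-tier proxy,
#'   evaluations, latent correlation, ladder, importance), `comparisons`,
#'   `manifest`.
#' @export
run_experiment <- function(config = experiment_config(), out_dir = NULL) {
  stopifnot(inherits(config, "experiment_config"))
  t0 <- Sys.time()

  building <- simulate_model_building_cohort(config$building)
  params <- fit_rri(building$cohort)
  scores <- score_rri(params, building$cohort)
  split <- split_train_test(building$cohort, config$train_fraction,
                            seed = derive_seed(config$seed, "split75"))
  train <- building$cohort[building$cohort$id %in% split$train, ]
  test <- building$cohort[building$cohort$id %in% split$test, ]

  validation <- simulate_validation_cohort(config$validation)
  long <- validation$longitudinal

  tier_results <- list()
  for (tier_name in config$tiers) {
    tier <- tier_spec(tier_name)
    tcfg <- config$tuner
    tcfg$seed <- derive_seed(config$seed, paste0("tune_", tier_name))
    tuned <- tune_proxy(train, scores, tier, tcfg)
    proxy <- fit_final(train, scores, tier, tuned$best_hyperparameters,
                       cv_rmse = tuned$cv_rmse, seed = tcfg$seed)
    eval_train <- evaluate_proxy(proxy, train, scores, split = "train_cv")
    eval_test <- evaluate_proxy(proxy, test, scores, split = "held_out")
    latent <- latent_correlation(params, test, stats::predict(proxy, test))

    baseline_scores <- stats::predict(proxy, validation$cohort)
    long_proxy <- long
    long_proxy$approx_cr <- baseline_scores[match(long$id, validation$cohort$id)]
    ladder <- run_ladder(long_proxy, ladder_spec("approx_cr"))

    tier_results[[tier_name]] <- list(
      tier = tier_name, proxy = proxy, tuning = tuned,
      eval_train = eval_train, eval_test = eval_test,
      latent_correlation = latent, ladder = ladder,
      importance = gain_importance(proxy),
      attributions = shap_attributions(proxy, train))
  }

  comparisons <- list()
  if (isTRUE(config$comparison_ladders)) {
    for (p in c("educ", "word_reading")) {
      comparisons[[p]] <- run_ladder(long, ladder_spec(p))
    }
  }

  result <- structure(list(config = config,
                           criterion_params = params,
                           criterion_scores = scores,
                           split = split,
                           tiers = tier_results,
                           comparisons = comparisons,
                           elapsed = as.numeric(difftime(Sys.time(), t0,
                                                         units = "secs"))),
                      class = "experiment_result")
  if (!is.null(out_dir)) {
    result$manifest <- write_experiment(result, out_dir)
  }
  invisible(result)
}

write_experiment <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  cfg <- result$config
  paths <- character(0)
  wr_csv <- function(df, name) {
    p <- file.path(out_dir, name)
    utils::write.csv(df, p, row.names = FALSE, na = "")
    paths <<- c(paths, p)
  }
  wr_json <- function(x, name) {
    p <- file.path(out_dir, name)
    jsonlite::write_json(x, p, auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         na = "null")
    paths <<- c(paths, p)
  }
  wr_csv(result$criterion_scores$scores, "criterion_scores.csv")
  wr_json(list(intercept = result$criterion_params$intercept,
               path_coefficients = as.list(result$criterion_params$path_coefficients),
               residual_variance = result$criterion_params$residual_variance,
               measurement_error_variance =
                 result$criterion_params$measurement_error_variance,
               n_used = result$criterion_params$n_used),
          "criterion_params.json")
  for (tier_name in names(result$tiers)) {
    tr <- result$tiers[[tier_name]]
    wr_csv(tr$tuning$log, sprintf("tuning_log_%s.csv", tier_name))
    wr_json(list(hyperparameters = tr$proxy$hyperparameters,
                 cv_rmse = tr$tuning$cv_rmse,
                 train_rmse = tr$eval_train$rmse,
                 heldout_rmse = tr$eval_test$rmse,
                 heldout_r = tr$eval_test$pearson_r,
                 latent_r = tr$latent_correlation$r,
                 latent_r_se = tr$latent_correlation$se),
            sprintf("proxy_%s.json", tier_name))
    wr_csv(tr$ladder$table, sprintf("ladder_%s.csv", tier_name))
    wr_csv(tr$importance, sprintf("importance_%s.csv", tier_name))
    wr_csv(beeswarm_export(tr$attributions), sprintf("beeswarm_%s.csv", tier_name))
  }
  for (p in names(result$comparisons)) {
    wr_csv(result$comparisons[[p]]$table, sprintf("ladder_comparison_%s.csv", p))
  }
  manifest <- list(
    package_version = as.character(utils::packageVersion("cogreserve")),
    seed = cfg$seed,
    stage_seeds = list(building = cfg$building$seed,
                       validation = cfg$validation$seed,
                       split = derive_seed(cfg$seed, "split75")),
    timestamp = format(Sys.time(), tz = "UTC"),
    files = as.list(tools::md5sum(paths)))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  manifest
}

#' Human-readable experiment report
#'
#' Renders a markdown summary of a completed run: per-tier accuracy
#' (cross-validated, training and held-out RMSE; held-out and latent
#' correlations), the moderation-ladder fit tables (# parameters, AIC, BIC,
#' logLik, deviance, chi-square increments, degrees of freedom, p-values),
#' and the top of each importance ranking. Regenerates byte-identically from
#' the same result.
#'
#' @param result An `experiment_result`.
#' @param path Optional file to write the markdown to.
#' @return The report as a character vector of lines, invisibly if written.
#' @export
report_experiment <- function(result, path = NULL) {
  stopifnot(inherits(result, "experiment_result"))
  fmt <- function(x, d = 3) formatC(x, digits = d, format = "f")
  lines <- c("# Cognitive reserve surrogate experiment", "",
             sprintf("Criterion: residual variance psi = %s on n = %d participants; scored factor scores standardized to mean 0, SD 1.",
                     fmt(result$criterion_params$residual_variance, 4),
                     result$criterion_params$n_used), "",
             "## Surrogate accuracy", "",
             "| Tier | CV RMSE | Train RMSE | Held-out RMSE | Held-out r | Latent r (SE) |",
             "|---|---|---|---|---|---|")
  for (tr in result$tiers) {
    lines <- c(lines, sprintf(
      "| %s | %s | %s | %s | %s | %s (%s) |",
      tr$tier, fmt(tr$tuning$cv_rmse), fmt(tr$eval_train$rmse),
      fmt(tr$eval_test$rmse), fmt(tr$eval_test$pearson_r),
      fmt(tr$latent_correlation$r), fmt(tr$latent_correlation$se)))
  }
  ladder_md <- function(tab, title) {
    out <- c("", sprintf("## %s", title), "",
             "| Label | Model | # Parameters | AIC | BIC | logLik | Deviance | Dchisq | Ddf | P | Comparison |",
             "|---|---|---|---|---|---|---|---|---|---|---|")
    for (i in seq_len(nrow(tab))) {
      out <- c(out, sprintf(
        "| %s | %s | %d | %s | %s | %s | %s | %s | %s | %s | %s |",
        tab$label[i], tab$model[i], tab$n_params[i], fmt(tab$AIC[i], 1),
        fmt(tab$BIC[i], 1), fmt(tab$logLik[i], 1), fmt(tab$deviance[i], 1),
        ifelse(is.na(tab$delta_chisq[i]), "-", fmt(tab$delta_chisq[i], 2)),
        ifelse(is.na(tab$delta_df[i]), "-", tab$delta_df[i]),
        ifelse(is.na(tab$p_value[i]), "-",
               ifelse(tab$p_value[i] < 0.01, "<0.01", fmt(tab$p_value[i], 2))),
        ifelse(is.na(tab$comparison[i]), "-", tab$comparison[i])))
    }
    out
  }
  for (tr in result$tiers) {
    lines <- c(lines, ladder_md(tr$ladder$table,
                                sprintf("Moderation ladder: %s tier", tr$tier)))
  }
  for (p in names(result$comparisons)) {
    lines <- c(lines, ladder_md(result$comparisons[[p]]$table,
                                sprintf("Moderation ladder: %s (comparison proxy)", p)))
  }
  lines <- c(lines, "", "## Variable importance (top 5 per tier)", "")
  for (tr in result$tiers) {
    top <- utils::head(tr$importance[order(tr$importance$rank), ], 5)
    lines <- c(lines, sprintf("- %s: %s", tr$tier,
                              paste(sprintf("%s (%.2f)", top$feature,
                                            top$importance), collapse = ", ")))
  }
  if (!is.null(path)) {
    writeLines(lines, path)
    return(invisible(lines))
  }
  lines
}
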