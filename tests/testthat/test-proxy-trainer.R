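test_that("the train/test split is a reproducible partition", {
  sim <- small_building()
  sp <- split_train_test(sim$cohort, 0.75, seed = 4L)
  expect_length(sp$train, 375)
  expect_length(sp$test, 125)
  expect_length(intersect(sp$train, sp$test), 0)
  expect_setequal(c(sp$train, sp$test), sim$cohort$id)
  expect_identical(sp, split_train_test(sim$cohort, 0.75, seed = 4L))
  expect_false(identical(sp, split_train_test(sim$cohort, 0.75, seed = 5L)))
  expect_error(split_train_test(sim$cohort, 1.2), "strictly between")
  expect_error(split_train_test(utils::head(sim$cohort, 5)), "at least 8")
})

test_that("the tuner honours its stopping contract and returns the argmin", {
  sim <- small_building()
  fs <- score_rri(fit_rri(sim$cohort), sim$cohort)
  one <- tune_proxy(sim$cohort, fs, "minimal", quick_tuner(max_iterations = 1L))
  expect_equal(nrow(one$log), 1L)
  expect_equal(one$cv_rmse, one$log$cv_rmse[1])

  res <- tune_proxy(sim$cohort, fs, "extended", quick_tuner(max_iterations = 8L))
  expect_lte(nrow(res$log), 8L)
  expect_equal(res$cv_rmse, min(res$log$cv_rmse, na.rm = TRUE))
  # early discontinuation: never more than `patience` candidates after the best
  best_at <- which.min(res$log$cv_rmse)
  expect_lte(nrow(res$log) - best_at, 8L)

  shallow <- tune_proxy(sim$cohort, fs, "extended",
                        quick_tuner(max_iterations = 6L, patience = 2L))
  best_at <- which.min(shallow$log$cv_rmse)
  expect_lte(nrow(shallow$log) - best_at, 2L)
})

test_that("a single-point search space is returned unchanged", {
  sim <- small_building()
  fs <- score_rri(fit_rri(sim$cohort), sim$cohort)
  space <- data.frame(name = c("max_depth", "nrounds"),
                      lower = c(3, 80), upper = c(3, 80),
                      scale = "linear", integer = TRUE)
  res <- tune_proxy(sim$cohort, fs, "minimal",
                    tuner_config(n_folds = 3, max_iterations = 2, patience = 2,
                                 search_space = space, seed = 1))
  expect_true(all(res$log$max_depth == 3))
  expect_true(all(res$log$nrounds == 80))
  expect_equal(res$best_hyperparameters$max_depth, 3)
  expect_error(tuner_config(search_space = default_search_space()[0, ]),
               "at least one")
})

test_that("cross-validated tuning beats the constant-mean predictor", {
  sim <- small_building()
  fs <- score_rri(fit_rri(sim$cohort), sim$cohort)
  res <- tune_proxy(sim$cohort, fs, "extended", quick_tuner(max_iterations = 3L))
  baseline <- stats::sd(fs$scores$rri)   # RMSE of predicting the mean
  expect_lt(res$cv_rmse, baseline)
})

test_that("fold assignment is a partition of the training rows", {
  sim <- small_building()
  fs <- score_rri(fit_rri(sim$cohort), sim$cohort)
  res <- tune_proxy(sim$cohort, fs, "minimal", quick_tuner(max_iterations = 1L,
                                                           n_folds = 5L))
  expect_length(res$folds, nrow(sim$cohort))
  expect_setequal(unique(res$folds), 1:5)
  expect_true(all(table(res$folds) >= floor(nrow(sim$cohort) / 5)))
})

test_that("training is deterministic and predictions are order-invariant", {
  sim <- small_building()
  fs <- score_rri(fit_rri(sim$cohort), sim$cohort)
  p1 <- quick_proxy(sim$cohort, fs, "extended", seed = 11L)
  p2 <- quick_proxy(sim$cohort, fs, "extended", seed = 11L)
  probe <- utils::head(sim$cohort, 50)
  expect_identical(predict(p1, probe), predict(p2, probe))
  feats <- assemble_features(probe, tier_spec("extended"))
  expect_equal(predict(p1, feats[, rev(names(feats))]), predict(p1, probe))
  expect_error(predict(p1, cbind(feats, bogus = 1)), "unknown feature")
})

test_that("missing values route through the trees without pre-imputation", {
  sim <- small_building()
  fs <- score_rri(fit_rri(sim$cohort), sim$cohort)
  px <- quick_proxy(sim$cohort, fs, "full", seed = 3L)
  feats <- assemble_features(utils::head(sim$cohort, 5), tier_spec("full"))
  feats[1, ] <- NA
  pred <- predict(px, feats)
  expect_true(all(is.finite(pred)))
  # an external cohort missing whole anthropometric columns still scores
  v <- simulate_validation_cohort(generative_config(n_participants = 60L,
                                                    seed = 13L))
  expect_true(all(is.na(v$cohort$waist)))
  expect_true(all(is.finite(predict(px, v$cohort))))
  # an all-missing training column warns but is retained
  co <- sim$cohort
  co$waist <- NA_real_
  expect_warning(pw <- quick_proxy(co, fs, "minimal", seed = 3L),
                 "entirely missing")
  expect_true("absi" %in% pw$feature_order)
})

test_that("a criterion equal to one feature is learned almost perfectly", {
  sim <- simulate_model_building_cohort(generative_config(
    n_participants = 1200L, seed = 14L))
  crit <- as.numeric(scale(sim$cohort$screener))
  sp <- split_train_test(sim$cohort, 0.75, seed = 2L)
  train <- sim$cohort[sim$cohort$id %in% sp$train, ]
  test <- sim$cohort[sim$cohort$id %in% sp$test, ]
  px <- quick_proxy(train, crit[match(train$id, sim$cohort$id)], "extended",
                    seed = 5L, nrounds = 400, eta = 0.3)
  ev <- evaluate_proxy(px, test, crit[match(test$id, sim$cohort$id)])
  expect_lt(ev$rmse, 0.05 * stats::sd(crit))
})

test_that("evaluation reports match their closed forms", {
  sim <- small_building()
  fs <- score_rri(fit_rri(sim$cohort), sim$cohort)
  y <- fs$scores$rri
  perfect <- evaluate_proxy(y, sim$cohort, fs)
  expect_equal(perfect$rmse, 0)
  expect_equal(perfect$pearson_r, 1)
  constant <- evaluate_proxy(rep(mean(y), length(y)), sim$cohort, fs)
  expect_equal(constant$rmse, sqrt(mean((y - mean(y))^2)))  # population SD
  expect_equal(constant$pearson_r, 0)
  expect_true(constant$degenerate)
  expect_error(evaluate_proxy(y[1:2], utils::head(sim$cohort, 2), fs$scores$rri[1:2]),
               "at least 3")
})
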