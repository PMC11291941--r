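#' Random train/test partition of a cohort
#'
#' Simple (unstratified) random split of participant ids, reproducible given
#' the seed. Defaults to the 75/25 convention.
#'
#' @param cohort Cohort data frame with an `id` column.
#' @param train_fraction Fraction assigned to training (0 < f < 1).
#' @param seed Integer seed.
#' @return List with `train` and `test` id vectors (disjoint, exhaustive).
#' @export
split_train_test <- function(cohort, train_fraction = 0.75, seed = 1L) {
  if (train_fraction <= 0 || train_fraction >= 1)
    stop("train_fraction must lie strictly between 0 and 1")
  ids <- cohort$id
  n <- length(ids)
  if (n < 8) stop("need at least 8 participants to split")
  n_train <- round(n * train_fraction)
  with_seed(derive_seed(seed, "split"), {
    train <- sort(sample(ids, n_train))
    list(train = train, test = sort(setdiff(ids, train)))
  })
}

#' Default hyperparameter search space for the boosted surrogate
#'
#' Conventional ranges: tree depth 2-8, learning rate 0.01-0.3 (log scale),
#' minimum child weight 1-20, row and column subsampling 0.5-1, number of
#' trees 100-1500, and L2 regularization 0.001-10 (log scale).
#'
#' @return Data frame with columns `name`, `lower`, `upper`, `scale`
#'   (`"linear"`/`"log"`), `integer`.
#' @export
default_search_space <- function() {
  data.frame(
    name = c("max_depth", "eta", "min_child_weight", "subsample",
             "colsample_bytree", "nrounds", "lambda"),
    lower = c(2, 0.01, 1, 0.5, 0.5, 100, 1e-3),
    upper = c(8, 0.30, 20, 1.0, 1.0, 1500, 10),
    scale = c("linear", "log", "linear", "linear", "linear", "linear", "log"),
    integer = c(TRUE, FALSE, FALSE, FALSE, FALSE, TRUE, FALSE),
    stringsAsFactors = FALSE)
}

#' Tuner configuration
#'
#' Cross-validated hyperparameter search settings: out-of-fold RMSE over a
#' fixed V-fold partition is the objective; the search runs for at most
#' `max_iterations` candidates and stops early after `patience` consecutive
#' candidates without improvement.
#'
#' @param n_folds Number of CV folds (default 10).
#' @param max_iterations Maximum candidates evaluated (default 200).
#' @param patience Consecutive non-improvements tolerated (default 100).
#' @param search_space See [default_search_space()].
#' @param seed Integer seed governing folds, the space-filling design, and
#'   candidate proposals.
#' @return A list of class `tuner_config`.
#' @export
tuner_config <- function(n_folds = 10L, max_iterations = 200L, patience = 100L,
                         search_space = default_search_space(), seed = 1L) {
  if (n_folds < 2) stop("n_folds must be >= 2")
  if (patience > max_iterations) stop("patience must be <= max_iterations")
  if (!nrow(search_space)) stop("search_space must contain at least one hyperparameter")
  structure(list(n_folds = as.integer(n_folds),
                 max_iterations = as.integer(max_iterations),
                 patience = as.integer(patience),
                 search_space = search_space,
                 objective = "rmse",
                 seed = as.integer(seed)),
            class = "tuner_config")
}

# Map unit-cube coordinates to hyperparameter values per the search space.
decode_candidate <- function(u, space) {
  v <- numeric(nrow(space))
  for (j in seq_len(nrow(space))) {
    lo <- space$lower[j]; hi <- space$upper[j]
    val <- if (space$scale[j] == "log") {
      exp(log(lo) + u[j] * (log(hi) - log(lo)))
    } else lo + u[j] * (hi - lo)
    if (space$integer[j]) val <- round(val)
    v[j] <- val
  }
  stats::setNames(as.list(v), space$name)
}

xgb_params <- function(hp, seed) {
  list(max_depth = as.integer(hp$max_depth %||% 4L),
       eta = hp$eta %||% 0.1,
       min_child_weight = hp$min_child_weight %||% 1,
       subsample = hp$subsample %||% 1,
       colsample_bytree = hp$colsample_bytree %||% 1,
       lambda = hp$lambda %||% 1,
       objective = "reg:squarederror",
       nthread = 1L,
       seed = as.integer(seed))
}

# Out-of-fold RMSE of one hyperparameter candidate over a fixed fold partition.
cv_rmse_candidate <- function(X, y, folds, hp, seed) {
  sq_err <- 0
  for (f in sort(unique(folds))) {
    hold <- folds == f
    dtrain <- xgboost::xgb.DMatrix(X[!hold, , drop = FALSE],
                                   label = y[!hold], missing = NA)
    fit <- xgboost::xgb.train(params = xgb_params(hp, seed), data = dtrain,
                              nrounds = as.integer(hp$nrounds %||% 300L),
                              verbose = 0)
    pred <- stats::predict(fit, xgboost::xgb.DMatrix(X[hold, , drop = FALSE],
                                                     missing = NA))
    sq_err <- sq_err + sum((y[hold] - pred)^2)
  }
  sqrt(sq_err / length(y))
}

#' Tune surrogate hyperparameters by cross-validated search
#'
#' Surrogate-guided ("Bayesian-style") hyperparameter search: an initial
#' space-filling Latin hypercube design is evaluated by out-of-fold RMSE on a
#' fixed V-fold partition of the training rows; subsequent candidates are
#' proposed by fitting a random-forest surrogate to the evaluated
#' (hyperparameters, RMSE) pairs and choosing, from a fresh Latin hypercube of
#' proposals, the point with the best predicted RMSE (with occasional random
#' exploration). The search stops at `max_iterations` candidates or after
#' `patience` consecutive candidates without improvement, and returns the
#' argmin of all logged candidates.
#'
#' @param train Training cohort rows (data frame).
#' @param criterion A [score_rri()] result, or a numeric criterion vector
#'   aligned to `train` rows.
#' @param tier A [tier_spec()] or tier name.
#' @param cfg A [tuner_config()].
#' @param ... Passed to [assemble_features()].
#' @return List of class `tuning_result`: `best_hyperparameters`, `cv_rmse`,
#'   `log` (one row per evaluated candidate), `folds`.
#' @export
tune_proxy <- function(train, criterion, tier = tier_spec("extended"),
                       cfg = tuner_config(), ...) {
  stopifnot(inherits(cfg, "tuner_config"))
  if (is.character(tier)) tier <- tier_spec(tier)
  y <- criterion_vector(criterion, train)
  feats <- assemble_features(train, tier, ...)
  X <- as.matrix(feats)
  if (nrow(X) < 2 * cfg$n_folds)
    stop("need at least 2 rows per fold to tune")
  space <- cfg$search_space
  k <- nrow(space)
  with_seed(derive_seed(cfg$seed, "tune"), {
    folds <- sample(rep_len(seq_len(cfg$n_folds), nrow(X)))
    n_init <- min(max(5L, k + 2L), cfg$max_iterations)
    design <- lhs::randomLHS(n_init, k)
    log_rows <- list()
    best <- Inf; best_hp <- NULL; stall <- 0L; it <- 0L
    eval_candidate <- function(u) {
      hp <- decode_candidate(u, space)
      rmse <- tryCatch(cv_rmse_candidate(X, y, folds, hp, cfg$seed),
                       error = function(e) NA_real_)
      it <<- it + 1L
      log_rows[[it]] <<- data.frame(iteration = it, as.data.frame(hp),
                                    cv_rmse = rmse)
      if (!is.finite(rmse)) {
        warning("non-finite CV RMSE; candidate discarded")
        stall <<- stall + 1L
        return(invisible(NULL))
      }
      if (rmse < best) {
        best <<- rmse; best_hp <<- hp; stall <<- 0L
      } else stall <<- stall + 1L
      invisible(NULL)
    }
    for (i in seq_len(n_init)) {
      if (it >= cfg$max_iterations || stall >= cfg$patience) break
      eval_candidate(design[i, ])
    }
    while (it < cfg$max_iterations && stall < cfg$patience) {
      done <- do.call(rbind, log_rows)
      done <- done[is.finite(done$cv_rmse), , drop = FALSE]
      props <- lhs::randomLHS(64L, k)
      pick <- if (nrow(done) >= 4 && stats::runif(1) > 0.2) {
        sur <- randomForest::randomForest(
          x = done[, space$name, drop = FALSE], y = done$cv_rmse,
          ntree = 100)
        cand_hp <- t(apply(props, 1, function(u) unlist(decode_candidate(u, space))))
        colnames(cand_hp) <- space$name
        which.min(stats::predict(sur, as.data.frame(cand_hp)))
      } else sample.int(64L, 1)              # exploration / cold start
      eval_candidate(props[pick, ])
    }
    if (is.null(best_hp)) stop("no candidate achieved a finite CV RMSE")
    structure(list(best_hyperparameters = best_hp, cv_rmse = best,
                   log = do.call(rbind, log_rows), folds = folds,
                   tier = tier, seed = cfg$seed),
              class = "tuning_result")
  })
}

criterion_vector <- function(criterion, cohort) {
  if (inherits(criterion, "factor_scores")) {
    idx <- match(cohort$id, criterion$scores$id)
    if (anyNA(idx)) stop("criterion scores missing for some cohort ids")
    criterion$scores$rri[idx]
  } else {
    if (length(criterion) != nrow(cohort))
      stop("criterion vector must align with cohort rows")
    as.numeric(criterion)
  }
}

#' Fit the final boosted surrogate on all training rows
#'
#' Missing feature values are left as `NA` and routed natively by the tree
#' learner (no pre-imputation). Deterministic given data and seeds
#' (single-threaded training).
#'
#' @param train Training cohort rows.
#' @param criterion Criterion scores (see [tune_proxy()]).
#' @param tier A [tier_spec()] or tier name.
#' @param hyperparameters Named list of tuned hyperparameters.
#' @param cv_rmse Optional cross-validated RMSE to record.
#' @param seed Integer seed.
#' @param ... Passed to [assemble_features()].
#' @return A list of class `trained_proxy`.
#' @export
fit_final <- function(train, criterion, tier, hyperparameters,
                      cv_rmse = NA_real_, seed = 1L, ...) {
  if (is.character(tier)) tier <- tier_spec(tier)
  y <- criterion_vector(criterion, train)
  feats <- assemble_features(train, tier, ...)
  X <- as.matrix(feats)
  all_missing <- colnames(X)[colSums(!is.na(X)) == 0]
  if (length(all_missing))
    warning("feature(s) entirely missing in training data: ",
            paste(all_missing, collapse = ", "))
  booster <- xgboost::xgb.train(
    params = xgb_params(hyperparameters, seed),
    data = xgboost::xgb.DMatrix(X, label = y, missing = NA),
    nrounds = as.integer(hyperparameters$nrounds %||% 300L),
    verbose = 0)
  structure(list(tier = tier, booster = booster,
                 feature_order = tier$feature_names,
                 hyperparameters = hyperparameters,
                 cv_rmse = cv_rmse, seed = seed,
                 assemble_args = list(...)),
            class = "trained_proxy")
}

#' Predict surrogate reserve scores
#'
#' Accepts either a raw cohort table (features are assembled internally) or a
#' data frame whose columns are exactly the proxy's features in any order.
#' Rows containing missing values — even entirely missing rows — receive
#' finite scores through the learner's default split directions.
#'
#' @param object A `trained_proxy`.
#' @param newdata Cohort or feature data frame.
#' @param ... Unused.
#' @return Numeric vector of predicted reserve scores.
#' @export
predict.trained_proxy <- function(object, newdata, ...) {
  nd_names <- names(newdata)
  if (setequal(nd_names, object$feature_order)) {
    feats <- newdata[object$feature_order]       # column order irrelevant
  } else if (all(object$feature_order %in% nd_names)) {
    stop("unknown feature key(s): ",
         paste(setdiff(nd_names, object$feature_order), collapse = ", "))
  } else {
    feats <- do.call(assemble_features,
                     c(list(newdata, object$tier), object$assemble_args))
  }
  X <- as.matrix(as.data.frame(feats)[object$feature_order])
  storage.mode(X) <- "double"
  stats::predict(object$booster, xgboost::xgb.DMatrix(X, missing = NA))
}

#' Evaluate surrogate predictions against the criterion
#'
#' @param proxy A `trained_proxy`, or a bare numeric vector of predictions
#'   aligned to `cohort` rows.
#' @param cohort Cohort rows to evaluate on.
#' @param criterion Criterion scores aligned to `cohort`.
#' @param split Label recorded in the report (`"train_cv"`, `"held_out"`,
#'   `"external"`).
#' @return A list of class `evaluation_report`: `rmse`, `pearson_r`, `n`,
#'   `split`, `degenerate` (TRUE when r is undefined and reported as 0).
#' @export
evaluate_proxy <- function(proxy, cohort, criterion, split = "held_out") {
  y <- criterion_vector(criterion, cohort)
  pred <- if (is.numeric(proxy)) {
    if (length(proxy) != nrow(cohort))
      stop("prediction vector must align with cohort rows")
    proxy
  } else stats::predict(proxy, cohort)
  keep <- !is.na(y) & !is.na(pred)
  y <- y[keep]; pred <- pred[keep]
  if (length(y) < 3) stop("need at least 3 evaluable rows")
  rmse <- sqrt(mean((y - pred)^2))
  degenerate <- stats::sd(pred) == 0 || stats::sd(y) == 0
  r <- if (degenerate) 0 else stats::cor(pred, y)
  structure(list(rmse = rmse, pearson_r = r, n = length(y),
                 split = split, degenerate = degenerate),
            class = "evaluation_report")
}

#' @export
#' @method print evaluation_report
print.evaluation_report <- function(x, ...) {
  cat(sprintf("[%s] n = %d, RMSE = %.4f, r = %.3f%s\n", x$split, x$n, x$rmse,
              x$pearson_r, if (x$degenerate) " (degenerate)" else ""))
  invisible(x)
}
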