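#' Specification of the nested moderation ladder
#'
#' Defines the four-stage sequence of longitudinal mixed models used to test
#' whether a reserve proxy moderates brain-cognition associations:
#' * E1 "Covariates Only": covariates and their time interactions, brain
#'   terms (baseline grey matter, grey-matter change, baseline-by-time), and
#'   moderation terms for the comparison proxies (education, word reading) so
#'   later stages isolate the tested proxy's increment.
#' * E2 "No Moderation": adds the proxy's main effects
#'   (`reserve`, `reserve:time`) — 2 terms.
#' * E3 "Intercept Moderation": adds `gm_baseline:reserve` — 1 term.
#' * E4 "Slope Moderation": adds `gm_baseline:reserve:time` and
#'   `gm_change:reserve` — 2 terms.
#'
#' @param reserve_var Column of the longitudinal table holding the proxy
#'   under test.
#' @param outcome,time Outcome and time columns.
#' @param covariates Baseline covariates (age is centred at `age_center`,
#'   education at `educ_center` internally).
#' @param brain_terms Brain variables (baseline level and change).
#' @param comparison_proxies Covariates whose own moderation terms are folded
#'   into E1; the tested proxy is dropped from this set automatically when it
#'   coincides with one of them.
#' @param age_center,educ_center Centring constants (years).
#' @return A list of class `ladder_spec`.
#' @export
ladder_spec <- function(reserve_var,
                        outcome = "ef", time = "time",
                        covariates = c("age0", "educ", "sex", "word_reading"),
                        brain_terms = c("gm_baseline", "gm_change"),
                        comparison_proxies = c("educ", "word_reading"),
                        age_center = 70, educ_center = 12) {
  # a proxy that is itself a baseline covariate enters only through the
  # reserve stages, otherwise the E2 terms would be rank-deficient
  comparison_proxies <- setdiff(comparison_proxies, reserve_var)
  covariates <- setdiff(covariates, reserve_var)
  structure(list(reserve_var = reserve_var, outcome = outcome, time = time,
                 covariates = covariates, brain_terms = brain_terms,
                 comparison_proxies = comparison_proxies,
                 age_center = age_center, educ_center = educ_center),
            class = "ladder_spec")
}

#' Build the four nested fixed-effect term sets
#'
#' @param spec A [ladder_spec()].
#' @return Named list of four character vectors of fixed-effect terms
#'   (`E1`-`E4`), each a strict superset of its predecessor; the stage
#'   increments are exactly 2, 1, and 2 terms.
#' @export
build_ladder <- function(spec) {
  stopifnot(inherits(spec, "ladder_spec"))
  tm <- spec$time
  cv <- spec$covariates
  e1 <- c(tm, cv, paste0(cv, ":", tm), spec$brain_terms,
          paste0(spec$brain_terms[1], ":", tm))
  for (p in spec$comparison_proxies) {
    e1 <- c(e1,
            paste0(p, ":", spec$brain_terms[1]),
            paste0(p, ":", spec$brain_terms[1], ":", tm),
            paste0(p, ":", spec$brain_terms[2]))
  }
  e1 <- unique(e1)
  stage2 <- c("reserve", paste0("reserve:", tm))
  stage3 <- paste0(spec$brain_terms[1], ":reserve")
  stage4 <- c(paste0(spec$brain_terms[1], ":reserve:", tm),
              paste0(spec$brain_terms[2], ":reserve"))
  if (any(c(stage2, stage3, stage4) %in% e1))
    stop("stage terms collide with baseline terms; rename reserve_var")
  list(E1 = e1, E2 = c(e1, stage2), E3 = c(e1, stage2, stage3),
       E4 = c(e1, stage2, stage3, stage4))
}

# Prepare the analysis frame: centred covariates, proxy renamed to `reserve`,
# listwise deletion over the union of ladder variables.
ladder_frame <- function(data, spec) {
  d <- data
  if (!spec$reserve_var %in% names(d))
    stop("reserve_var column not found: ", spec$reserve_var)
  d$reserve <- d[[spec$reserve_var]]
  if ("age0" %in% spec$covariates) d$age0 <- d$age0 - spec$age_center
  if ("educ" %in% spec$covariates) d$educ <- d$educ - spec$educ_center
  vars <- unique(c(spec$outcome, spec$time, spec$covariates, spec$brain_terms,
                   "reserve", "id"))
  keep <- stats::complete.cases(d[vars])
  d <- d[keep, , drop = FALSE]
  attr(d, "n_dropped") <- sum(!keep)
  d
}

#' Fit one longitudinal linear mixed model by maximum likelihood
#'
#' Gaussian linear mixed model with correlated random intercept and random
#' time slope per participant, estimated by ML (not REML) so that
#' likelihood-ratio tests of fixed-effect structures are valid. If the
#' random-effect covariance is singular the model is refitted with a diagonal
#' (uncorrelated) structure and flagged.
#'
#' @param data Longitudinal data frame (one row per participant-visit) with
#'   an `id` column.
#' @param terms Character vector of fixed-effect terms.
#' @param outcome,time Column names.
#' @return A list of class `lmm_fit`: `fixed_effects` (estimate, se),
#'   `random_covariance` (2x2), `sigma2`, `loglik`, `deviance`, `n_params`,
#'   `n_obs`, `converged`, `singular`, and the underlying `model`.
#' @export
fit_lmm <- function(data, terms, outcome = "ef", time = "time") {
  if (length(unique(data$id)) < 10)
    stop("need >= 10 participants")
  if (max(table(data$id)) < 2)
    stop("need >= 2 visits for at least some participants")
  rhs <- paste(c(terms, sprintf("(1 + %s | id)", time)), collapse = " + ")
  form <- stats::as.formula(paste(outcome, "~", rhs))
  ctrl <- lme4::lmerControl(check.conv.singular = "ignore",
                            check.scaleX = "ignore",
                            calc.derivs = FALSE)
  fit <- lme4::lmer(form, data = data, REML = FALSE, control = ctrl)
  singular <- lme4::isSingular(fit, tol = 1e-5)
  if (singular) {
    rhs2 <- paste(c(terms, sprintf("(1 + %s || id)", time)), collapse = " + ")
    fit <- lme4::lmer(stats::as.formula(paste(outcome, "~", rhs2)),
                      data = data, REML = FALSE, control = ctrl)
  }
  conv_msgs <- fit@optinfo$conv$lme4$messages
  converged <- is.null(conv_msgs) ||
    !any(grepl("failed to converge", conv_msgs, ignore.case = TRUE))
  vc <- lme4::VarCorr(fit)$id
  rc <- matrix(0, 2, 2,
               dimnames = list(c("(Intercept)", time), c("(Intercept)", time)))
  if (!is.null(vc) && all(dim(vc) == 2)) {
    rc[, ] <- vc[, ]
  } else {
    # doubled-bar fallback: variance components reported separately
    for (g in lme4::VarCorr(fit)) {
      nm <- rownames(g)
      rc[nm, nm] <- g[, , drop = FALSE]
    }
  }
  fe <- lme4::fixef(fit)
  se <- sqrt(diag(as.matrix(stats::vcov(fit))))
  n_theta <- length(lme4::getME(fit, "theta"))
  n_params <- length(fe) + n_theta + 1L          # fixed + var-cov + residual
  ll <- as.numeric(stats::logLik(fit))
  structure(list(fixed_effects = data.frame(term = names(fe), estimate = fe,
                                            se = se, row.names = NULL),
                 random_covariance = rc,
                 sigma2 = stats::sigma(fit)^2,
                 loglik = ll, deviance = -2 * ll,
                 n_params = n_params,
                 n_obs = stats::nobs(fit),
                 converged = converged, singular = singular,
                 terms = terms, outcome = outcome, time = time,
                 model = fit),
            class = "lmm_fit")
}

#' Direct marginal log-likelihood of a fitted mixed model
#'
#' Evaluates, from first principles, the marginal multivariate-normal
#' log-density of the data at the parameters of an [fit_lmm()] result:
#' for each participant, `V_i = Z_i Psi Z_i' + sigma^2 I` with
#' `Z_i = [1, t_i]`, and the log-density of `y_i` around `X_i beta` is
#' accumulated. Serves as an independent check on the optimizer-reported
#' log-likelihood.
#'
#' @param fit An `lmm_fit`.
#' @return The summed marginal log-likelihood.
#' @export
lmm_loglik_direct <- function(fit) {
  m <- fit$model
  X <- lme4::getME(m, "X")
  y <- lme4::getME(m, "y")
  fr <- m@frame
  beta <- lme4::fixef(m)
  mu <- drop(X %*% beta)
  psi <- fit$random_covariance
  s2 <- fit$sigma2
  ids <- fr[["id"]]
  tt <- fr[[fit$time]]
  ll <- 0
  for (g in unique(ids)) {
    sel <- which(ids == g)
    Z <- cbind(1, tt[sel])
    V <- Z %*% psi %*% t(Z) + diag(s2, length(sel))
    r <- y[sel] - mu[sel]
    ch <- chol(V)
    ll <- ll - 0.5 * (length(sel) * log(2 * pi) + 2 * sum(log(diag(ch))) +
                        sum(backsolve(ch, r, transpose = TRUE)^2))
  }
  ll
}

#' Likelihood-ratio test of two nested mixed-model fits
#'
#' @param restricted,full `lmm_fit` objects on identical rows.
#' @param labels Length-2 character vector naming the two models.
#' @return A list of class `lrt_result`: `delta_deviance`, `delta_df`,
#'   `p_value`, `comparison`.
#' @export
lrt <- function(restricted, full, labels = c("restricted", "full")) {
  if (restricted$n_obs != full$n_obs)
    stop("LRT requires identical row sets")
  dd <- restricted$deviance - full$deviance
  if (dd < 0) {
    if (dd > -1e-6) {
      warning("small negative deviance difference clamped to 0")
      dd <- 0
    } else stop("full model fits worse than restricted model (optimizer failure)")
  }
  ddf <- full$n_params - restricted$n_params
  p <- if (ddf > 0) stats::pchisq(dd, df = ddf, lower.tail = FALSE) else
    if (dd == 0) 1 else NA_real_
  structure(list(delta_deviance = dd, delta_df = ddf, p_value = p,
                 comparison = sprintf("%s versus %s", labels[2], labels[1])),
            class = "lrt_result")
}

#' Run the full moderation ladder
#'
#' Fits the four nested models on a common listwise-complete row set and
#' compares consecutive stages by likelihood-ratio tests (E2 vs E1,
#' E3 vs E2, E4 vs E3). Non-converged stages void their comparisons with a
#' warning.
#'
#' @param data Longitudinal table (see [simulate_validation_cohort()])
#'   augmented with the proxy column named in `spec`.
#' @param spec A [ladder_spec()].
#' @return A list of class `ladder_fit`: `fits` (four `lmm_fit`s), `lrt`
#'   (data frame with `comparison`, `delta_chisq`, `delta_df`, `p_value`),
#'   `table` (a fit-statistics table with # parameters, AIC, BIC, logLik,
#'   deviance), `n_obs`, `n_dropped`.
#' @export
run_ladder <- function(data, spec) {
  stopifnot(inherits(spec, "ladder_spec"))
  terms <- build_ladder(spec)
  d <- ladder_frame(data, spec)
  fits <- lapply(terms, function(tt)
    fit_lmm(d, tt, outcome = spec$outcome, time = spec$time))
  labels <- c("Covariates Only", "No Moderation", "Intercept Moderation",
              "Slope Moderation")
  lrts <- vector("list", 3)
  for (i in 1:3) {
    if (!fits[[i]]$converged || !fits[[i + 1]]$converged) {
      warning(sprintf("stage %s did not converge; comparison unavailable",
                      names(terms)[i + 1]))
      lrts[[i]] <- list(delta_deviance = NA_real_, delta_df = NA_integer_,
                        p_value = NA_real_,
                        comparison = sprintf("%s versus %s", names(terms)[i + 1],
                                             names(terms)[i]))
    } else {
      lrts[[i]] <- lrt(fits[[i]], fits[[i + 1]],
                       labels = names(terms)[i:(i + 1)])
    }
  }
  tab <- data.frame(
    label = names(terms), model = labels,
    n_params = vapply(fits, `[[`, integer(1), "n_params"),
    AIC = vapply(fits, function(f) f$deviance + 2 * f$n_params, numeric(1)),
    BIC = vapply(fits, function(f) f$deviance + f$n_params * log(f$n_obs),
                 numeric(1)),
    logLik = vapply(fits, `[[`, numeric(1), "loglik"),
    deviance = vapply(fits, `[[`, numeric(1), "deviance"),
    delta_chisq = c(NA, vapply(lrts, function(l) l$delta_deviance, numeric(1))),
    delta_df = c(NA, vapply(lrts, function(l) as.numeric(l$delta_df), numeric(1))),
    p_value = c(NA, vapply(lrts, function(l) l$p_value, numeric(1))),
    comparison = c(NA, vapply(lrts, function(l) l$comparison, character(1))))
  structure(list(fits = fits,
                 lrt = tab[-1, c("comparison", "delta_chisq", "delta_df",
                                 "p_value")],
                 table = tab, spec = spec,
                 n_obs = fits[[1]]$n_obs,
                 n_dropped = attr(d, "n_dropped")),
            class = "ladder_fit")
}

#' Fixed-effects trajectory predictions for a reference profile
#'
#' Predicts executive-function trajectories (fixed effects only, random
#' effects set to zero) for a hypothetical reference participant over a grid
#' of atrophy rates and reserve levels, with `gm_change = rate * time`.
#'
#' @param fit An `lmm_fit` (typically the E4 stage).
#' @param profile Named list of covariate values on the *original* scale used
#'   when fitting (e.g. already-centred age if the ladder centred it); any
#'   model variable absent from the profile defaults to 0.
#' @param atrophy_rates Grey-matter change rates in SD units per year.
#' @param reserve_levels Proxy values at which to predict.
#' @param times Prediction time grid (years).
#' @return Data frame: `time`, `atrophy_rate`, `reserve_level`, `predicted_ef`.
#' @export
predict_trajectories <- function(fit, profile = list(),
                                 atrophy_rates = c(-0.05, -0.10, -0.15),
                                 reserve_levels = c(-1, 0, 1),
                                 times = seq(0, 5, by = 0.5)) {
  stopifnot(inherits(fit, "lmm_fit"))
  if (!length(atrophy_rates)) stop("atrophy_rates must be non-empty")
  if (!fit$converged) stop("cannot predict from a non-converged fit")
  grid <- expand.grid(time = times, atrophy_rate = atrophy_rates,
                      reserve_level = reserve_levels,
                      KEEP.OUT.ATTRS = FALSE)
  nd <- grid
  names(nd)[names(nd) == "reserve_level"] <- "reserve"
  nd$gm_change <- nd$atrophy_rate * nd$time
  vars <- setdiff(all.vars(stats::formula(fit$model)),
                  c(fit$outcome, "id", names(nd)))
  for (v in vars) nd[[v]] <- profile[[v]] %||% 0
  nd$id <- NA
  grid$predicted_ef <- stats::predict(fit$model, newdata = nd, re.form = NA,
                                      allow.new.levels = TRUE)
  grid
}
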