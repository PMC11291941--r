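#' Specification of the residual reserve latent model
#'
#' Defines the single-indicator linear-Gaussian latent decomposition of the
#' episodic memory composite: memory is regressed on brain variables
#' (grey-matter signature, log WMH), demographics (sex, Black/AA, Hispanic
#' indicators; White is the reference), and test-exposure terms (prior
#' exposure, Spanish-language administration, and their interaction). The
#' residual latent variance is the reserve criterion. Education is
#' deliberately excluded by default so the residual retains
#' education-related variance and education can later be compared against
#' other predictors of the residual.
#'
#' @param memory_indicator Column holding the memory composite.
#' @param brain_predictors,demographic_predictors,exposure_predictors
#'   Predictor column names.
#' @param include_exposure_interaction Include the prior-exposure by Spanish
#'   interaction term.
#' @param include_education Add education as a predictor of memory
#'   (default `FALSE`).
#' @param measurement_error_variance Known variance of measurement error in
#'   the memory indicator (0 gives the exact least-squares case).
#' @return A list of class `rri_spec`.
#' @export
rri_spec <- function(memory_indicator = "memory",
                     brain_predictors = c("gm_signature", "log_wmh"),
                     demographic_predictors = c("sex", "black_aa", "hispanic"),
                     exposure_predictors = c("prior_exposure", "spanish"),
                     include_exposure_interaction = TRUE,
                     include_education = FALSE,
                     measurement_error_variance = 0) {
  if (measurement_error_variance < 0)
    stop("measurement_error_variance must be >= 0")
  structure(list(memory_indicator = memory_indicator,
                 brain_predictors = brain_predictors,
                 demographic_predictors = demographic_predictors,
                 exposure_predictors = exposure_predictors,
                 include_exposure_interaction = include_exposure_interaction,
                 include_education = include_education,
                 measurement_error_variance = measurement_error_variance),
            class = "rri_spec")
}

rri_design <- function(cohort, spec) {
  preds <- c(spec$brain_predictors, spec$demographic_predictors,
             spec$exposure_predictors,
             if (spec$include_education) "education")
  missing_cols <- setdiff(c(spec$memory_indicator, preds), names(cohort))
  if (length(missing_cols))
    stop("columns not found in cohort: ", paste(missing_cols, collapse = ", "))
  X <- as.matrix(cohort[preds])
  storage.mode(X) <- "double"
  if (spec$include_exposure_interaction && length(spec$exposure_predictors) >= 2) {
    e1 <- spec$exposure_predictors[1]; e2 <- spec$exposure_predictors[2]
    X <- cbind(X, cohort[[e1]] * cohort[[e2]])
    colnames(X)[ncol(X)] <- paste0(e1, "_x_", e2)
  }
  X <- cbind(`(Intercept)` = 1, X)
  list(X = X, y = as.numeric(cohort[[spec$memory_indicator]]))
}

#' Fit the residual reserve latent model
#'
#' Maximum-likelihood estimation of the linear-Gaussian model
#' `memory = intercept + sum(coef * predictor) + RRI (+ measurement error)`.
#' In the single-indicator case the path coefficients coincide exactly with
#' ordinary least squares; the latent residual variance `psi` is the ML
#' residual variance (divisor `n`) minus any known measurement-error variance
#' (clamped at 0). Rows with missing memory or predictors are dropped listwise
#' with a message.
#'
#' @param cohort Cohort data frame.
#' @param spec An [rri_spec()].
#' @return A list of class `rri_params`: `path_coefficients`, `intercept`,
#'   `residual_variance` (psi), `measurement_error_variance`, `n_used`,
#'   `loglik`, and the `rri_spec` used.
#' @export
fit_rri <- function(cohort, spec = rri_spec()) {
  stopifnot(inherits(spec, "rri_spec"))
  d <- rri_design(cohort, spec)
  keep <- stats::complete.cases(d$X, d$y)
  n_dropped <- sum(!keep)
  if (n_dropped > 0)
    message(sprintf("fit_rri: dropping %d incomplete row(s) listwise", n_dropped))
  X <- d$X[keep, , drop = FALSE]
  y <- d$y[keep]
  n <- length(y)
  if (n <= ncol(X) + 2)
    stop(sprintf("too few complete rows (%d) for %d predictors", n, ncol(X) - 1))
  qr_x <- qr(X)
  if (qr_x$rank < ncol(X)) {
    bad <- colnames(X)[qr_x$pivot[(qr_x$rank + 1):ncol(X)]]
    stop("rank-deficient design; collinear columns: ", paste(bad, collapse = ", "))
  }
  beta <- qr.coef(qr_x, y)
  resid <- y - drop(X %*% beta)
  sigma2 <- sum(resid^2) / n                       # ML divisor n
  psi <- max(sigma2 - spec$measurement_error_variance, 0)
  loglik <- -n / 2 * (log(2 * pi * sigma2) + 1)
  structure(list(path_coefficients = beta[-1],
                 intercept = beta[[1]],
                 residual_variance = psi,
                 measurement_error_variance = spec$measurement_error_variance,
                 n_used = n, n_dropped = n_dropped,
                 loglik = loglik, spec = spec),
            class = "rri_params")
}

#' @export
#' @method print rri_params
print.rri_params <- function(x, ...) {
  cat("Residual reserve latent model (single indicator)\n")
  cat(sprintf("  n = %d (dropped %d), psi = %.4f, sigma_m^2 = %.4f\n",
              x$n_used, x$n_dropped, x$residual_variance,
              x$measurement_error_variance))
  print(round(c(`(Intercept)` = x$intercept, x$path_coefficients), 4))
  invisible(x)
}

#' Score the residual reserve index
#'
#' Computes regression-method (posterior mean) factor scores of the latent
#' residual under the fitted Gaussian model: the raw memory residual shrunk by
#' `psi / (psi + sigma_m^2)`, then standardized to mean 0, SD 1 across scored
#' participants. With zero measurement error the unstandardized score is
#' exactly the least-squares residual and determinacy is 1. Participants with
#' missing predictors receive `NA` scores (counted in a message).
#'
#' @param params An [fit_rri()] result.
#' @param cohort Cohort data frame to score (defaults may differ from the
#'   fitting cohort).
#' @return A list of class `factor_scores`: data frame `scores`
#'   (`id`, `rri`, `raw_residual`, `missing`), `determinacy`, and the
#'   centring/scaling used.
#' @export
score_rri <- function(params, cohort) {
  stopifnot(inherits(params, "rri_params"))
  d <- rri_design(cohort, params$spec)
  complete <- stats::complete.cases(d$X, d$y)
  if (any(!complete))
    message(sprintf("score_rri: %d participant(s) missing data; scores set NA",
                    sum(!complete)))
  beta <- c(params$intercept, params$path_coefficients)
  raw <- rep(NA_real_, nrow(d$X))
  raw[complete] <- d$y[complete] - drop(d$X[complete, , drop = FALSE] %*% beta)
  psi <- params$residual_variance
  sm2 <- params$measurement_error_variance
  determinacy <- if (psi + sm2 > 0) psi / (psi + sm2) else 1
  post <- determinacy * raw
  centre <- mean(post, na.rm = TRUE)
  scale <- stats::sd(post, na.rm = TRUE)
  if (!is.finite(scale) || scale == 0) scale <- 1   # degenerate: constant scores
  scores <- data.frame(
    id = if ("id" %in% names(cohort)) cohort$id else seq_len(nrow(cohort)),
    rri = (post - centre) / scale,
    raw_residual = raw,
    missing = !complete)
  structure(list(scores = scores, determinacy = determinacy,
                 centre = centre, scale = scale, params = params),
            class = "factor_scores")
}

#' Correlation between the latent reserve residual and a proxy score
#'
#' Estimates, by one-parameter maximum likelihood with every other parameter
#' held fixed at its previously estimated value, the correlation between the
#' latent residual and an observed proxy. The observed residual's variance is
#' fixed at `psi + sigma_m^2`, the proxy's variance at its divisor-n sample
#' variance, and the single free parameter is the latent correlation `rho`
#' (implying observed correlation `rho * sqrt(determinacy)`). With zero
#' measurement error the estimate equals the Pearson correlation between
#' proxy and raw residual; in general it equals the disattenuated Pearson
#' correlation at large n. The standard error comes from the observed
#' information (numerical second derivative at the maximum).
#'
#' @param params An [fit_rri()] result (all parameters frozen).
#' @param cohort Cohort data frame (scored internally).
#' @param proxy_scores Numeric vector aligned to `cohort` rows.
#' @return A list: `r` (latent correlation), `se`, `n`, `pearson_observed`.
#' @export
latent_correlation <- function(params, cohort, proxy_scores) {
  stopifnot(inherits(params, "rri_params"))
  if (length(proxy_scores) != nrow(cohort))
    stop("proxy_scores must align with cohort rows")
  fs <- suppressMessages(score_rri(params, cohort))
  raw <- fs$scores$raw_residual
  keep <- !is.na(raw) & !is.na(proxy_scores)
  x <- proxy_scores[keep]; y <- raw[keep]
  n <- length(x)
  if (n < 3) stop("need at least 3 complete proxy/residual pairs")
  if (stats::var(x) == 0) stop("proxy has zero variance")
  psi <- params$residual_variance
  sm2 <- params$measurement_error_variance
  det_ <- fs$determinacy
  sx <- sqrt(mean((x - mean(x))^2))                    # divisor-n moments
  sy_fixed <- sqrt(psi + sm2)
  xs <- (x - mean(x)) / sx
  ys <- (y - mean(y)) / sy_fixed
  s11 <- mean(xs^2); s22 <- mean(ys^2); s12 <- mean(xs * ys)
  # profile loglik in the observed-scale correlation c = rho * sqrt(determinacy);
  # additive constants (scale terms) omitted as they do not move the maximum
  loglik_c <- function(cc) {
    -n / 2 * log(1 - cc^2) -
      n / (2 * (1 - cc^2)) * (s11 - 2 * cc * s12 + s22)
  }
  # the score equation dl/dc = 0 is the cubic
  #   c^3 - s12 c^2 - (1 - s11 - s22) c - s12 = 0;
  # take the real root in [-1, 1] with the highest likelihood
  roots <- polyroot(c(-s12, -(1 - s11 - s22), -s12, 1))
  real <- Re(roots[abs(Im(roots)) < 1e-8])
  real <- real[abs(real) <= 1 + 1e-12]
  cand <- clamp(real, -1, 1)
  if (!length(cand)) {                      # numerically degenerate: fall back
    cand <- stats::optimize(loglik_c, c(-0.9999, 0.9999), maximum = TRUE,
                            tol = 1e-10)$maximum
  }
  ll <- vapply(cand, function(cc) if (abs(cc) < 1) loglik_c(cc) else
    loglik_c(sign(cc) * (1 - 1e-12)), numeric(1))
  c_hat <- cand[which.max(ll)]
  if (abs(c_hat) >= 1 - 1e-10) {
    se_c <- 0                               # boundary: information diverges
  } else {
    h <- 1e-5
    d2 <- (loglik_c(c_hat + h) - 2 * loglik_c(c_hat) + loglik_c(c_hat - h)) / h^2
    se_c <- if (is.finite(d2) && d2 < 0) sqrt(-1 / d2) else NA_real_
  }
  r <- c_hat / sqrt(det_)
  se <- se_c / sqrt(det_)
  if (is.finite(r) && abs(r) > 1) {
    warning("disattenuated correlation exceeded 1 in magnitude; clamped")
    r <- sign(r)
  }
  list(r = r, se = se, n = n,
       pearson_observed = stats::cor(x, y))
}
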