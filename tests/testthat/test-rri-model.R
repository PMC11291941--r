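test_that("single-indicator fit equals the normal-equations solution exactly", {
  sim <- small_building()
  params <- fit_rri(sim$cohort)
  X <- rri_design_matrix(sim$cohort)
  beta_oracle <- solve(crossprod(X), crossprod(X, sim$cohort$memory))
  expect_lt(max(abs(c(params$intercept, params$path_coefficients) -
                      drop(beta_oracle))), 1e-10)
  res <- sim$cohort$memory - drop(X %*% beta_oracle)
  expect_lt(abs(params$residual_variance - mean(res^2)), 1e-10)  # ML divisor n
})

test_that("path coefficients recover the generative truth at large n", {
  cfg <- generative_config(n_participants = 100000L, seed = 21L)
  sim <- simulate_model_building_cohort(cfg)
  params <- fit_rri(sim$cohort)
  fit <- stats::lm(memory ~ gm_signature + log_wmh + sex + black_aa + hispanic +
                     prior_exposure * spanish, data = sim$cohort)
  se <- summary(fit)$coefficients[, "Std. Error"]
  truth <- cfg$memory_coeffs
  expect_lt(abs(params$path_coefficients[["gm_signature"]] -
                  truth[["gm_signature"]]), 3 * se[["gm_signature"]])
  expect_lt(abs(params$path_coefficients[["log_wmh"]] - truth[["log_wmh"]]),
            3 * se[["log_wmh"]])
  expect_lt(abs(params$path_coefficients[["sex"]] - truth[["sex"]]),
            3 * se[["sex"]])
  # psi estimates reserve variance plus memory noise
  expect_lt(abs(params$residual_variance -
                  (cfg$reserve_sd^2 + cfg$noise_sds[["memory"]]^2)), 0.02)
})

test_that("degenerate and malformed designs are rejected informatively", {
  sim <- small_building()
  co <- sim$cohort
  co$memory <- 1.5
  params <- fit_rri(co)
  expect_true(all(abs(params$path_coefficients) < 1e-10))
  expect_equal(params$residual_variance, 0)
  co2 <- sim$cohort
  co2$log_wmh <- co2$gm_signature          # exact collinearity
  expect_error(fit_rri(co2), "collinear")
  expect_error(fit_rri(utils::head(sim$cohort, 8)), "too few")
  expect_error(fit_rri(sim$cohort[, setdiff(names(sim$cohort), "log_wmh")]),
               "log_wmh")
})

test_that("listwise deletion is applied and counted", {
  sim <- small_building()
  co <- sim$cohort
  co$memory[1:7] <- NA
  expect_message(params <- fit_rri(co), "7 incomplete")
  expect_equal(params$n_used, nrow(co) - 7L)
  expect_message(fs <- score_rri(params, co), "7 participant")
  expect_equal(sum(is.na(fs$scores$rri)), 7L)
  expect_equal(sum(fs$scores$missing), 7L)
})

test_that("zero-error factor scores are the regression residuals, standardized", {
  sim <- small_building()
  params <- fit_rri(sim$cohort)
  fs <- score_rri(params, sim$cohort)
  X <- rri_design_matrix(sim$cohort)
  res <- sim$cohort$memory - drop(X %*% solve(crossprod(X),
                                              crossprod(X, sim$cohort$memory)))
  expect_lt(max(abs(fs$scores$raw_residual - res)), 1e-10)
  expect_lt(abs(mean(fs$scores$rri)), 1e-9)
  expect_lt(abs(stats::sd(fs$scores$rri) - 1), 1e-9)
  expect_equal(fs$determinacy, 1)
})

test_that("measurement-error scores match a conditional-Gaussian oracle", {
  sim <- small_building()
  sm2 <- 0.3
  co <- sim$cohort
  set.seed(99)
  co$memory <- co$memory + stats::rnorm(nrow(co), 0, sqrt(sm2))
  params <- fit_rri(co, rri_spec(measurement_error_variance = sm2))
  fs <- score_rri(params, co)
  expect_lt(fs$determinacy, 1)
  # oracle: posterior mean of the latent by direct numerical integration of
  # the conditional Gaussian, participant by participant
  psi <- params$residual_variance
  post_oracle <- vapply(fs$scores$raw_residual[1:40], function(r) {
    joint <- function(u) stats::dnorm(u, 0, sqrt(psi)) *
      stats::dnorm(r - u, 0, sqrt(sm2))
    num <- stats::integrate(function(u) u * joint(u), -10, 10,
                            rel.tol = 1e-12)$value
    den <- stats::integrate(joint, -10, 10, rel.tol = 1e-12)$value
    num / den
  }, numeric(1))
  post_impl <- fs$determinacy * fs$scores$raw_residual[1:40]
  expect_lt(max(abs(post_impl - post_oracle)), 1e-8)
})

test_that("factor scores are invariant to affine predictor rescaling", {
  sim <- small_building()
  fs1 <- score_rri(fit_rri(sim$cohort), sim$cohort)
  co2 <- sim$cohort
  co2$gm_signature <- 10 * co2$gm_signature + 5
  co2$log_wmh <- -2 * co2$log_wmh
  fs2 <- score_rri(fit_rri(co2), co2)
  expect_lt(max(abs(fs1$scores$rri - fs2$scores$rri)), 1e-9)
})

test_that("the ML solution maximizes the Gaussian log-likelihood", {
  sim <- small_building()
  params <- fit_rri(sim$cohort)
  X <- rri_design_matrix(sim$cohort)
  y <- sim$cohort$memory
  loglik <- function(beta, s2) sum(stats::dnorm(y, drop(X %*% beta), sqrt(s2),
                                                log = TRUE))
  beta_hat <- c(params$intercept, params$path_coefficients)
  ll_hat <- loglik(beta_hat, params$residual_variance)
  expect_equal(ll_hat, params$loglik, tolerance = 1e-8)
  set.seed(1)
  for (i in 1:20) {
    expect_gt(ll_hat, loglik(beta_hat + stats::rnorm(length(beta_hat), 0, 0.05),
                             params$residual_variance * stats::runif(1, 0.8, 1.2)))
  }
})

test_that("latent correlation: self-correlation, null, and disattenuation identity", {
  sim <- small_building()
  params <- fit_rri(sim$cohort)
  fs <- score_rri(params, sim$cohort)
  self <- latent_correlation(params, sim$cohort, fs$scores$rri)
  expect_equal(self$r, 1)

  big <- simulate_model_building_cohort(generative_config(
    n_participants = 100000L, seed = 22L))
  pb <- fit_rri(big$cohort)
  set.seed(123)
  noise <- stats::rnorm(100000L)
  null_r <- latent_correlation(pb, big$cohort, noise)
  expect_lt(abs(null_r$r), 0.02)
  expect_error(latent_correlation(pb, big$cohort, rep(1, 100000L)), "variance")

  # measurement-error case against two independent oracles
  sm2 <- 0.4
  co <- big$cohort
  set.seed(7)
  co$memory <- co$memory + stats::rnorm(nrow(co), 0, sqrt(sm2))
  pm <- fit_rri(co, rri_spec(measurement_error_variance = sm2))
  fsm <- score_rri(pm, co)
  proxy <- big$latents$reserve + stats::rnorm(nrow(co), 0, 0.6)
  est <- latent_correlation(pm, co, proxy)
  disattenuated <- stats::cor(proxy, fsm$scores$raw_residual) /
    sqrt(fsm$determinacy)
  expect_equal(est$r, disattenuated, tolerance = 0.01)
  # numeric one-parameter likelihood maximization oracle
  x <- scale(proxy, scale = FALSE); y <- fsm$scores$raw_residual
  y <- y - mean(y)
  sx <- sqrt(mean(x^2)); sy <- sqrt(pm$residual_variance + sm2)
  nll <- function(cc) {
    S <- matrix(c(1, cc, cc, 1), 2)
    z <- cbind(x / sx, y / sy)
    0.5 * nrow(z) * determinant(S)$modulus +
      0.5 * sum((z %*% solve(S)) * z)
  }
  opt <- stats::optimize(nll, c(-0.99, 0.99), tol = 1e-9)
  expect_equal(est$r, opt$minimum / sqrt(fsm$determinacy), tolerance = 1e-4)
  expect_true(is.finite(est$se) && est$se > 0)
})

test_that("zero-error latent correlation equals the Pearson correlation", {
  sim <- small_building()
  params <- fit_rri(sim$cohort)
  fs <- score_rri(params, sim$cohort)
  set.seed(31)
  proxy <- fs$scores$rri + stats::rnorm(nrow(sim$cohort), 0, 1.2)
  est <- latent_correlation(params, sim$cohort, proxy)
  expect_equal(est$r, stats::cor(proxy, fs$scores$raw_residual),
               tolerance = 1e-9)
})
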