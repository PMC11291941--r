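test_that("simulation is deterministic given config and has the right shape", {
  cfg <- generative_config(n_participants = 500L, seed = 1L)
  a <- simulate_model_building_cohort(cfg)
  b <- simulate_model_building_cohort(cfg)
  expect_identical(a, b)
  expect_equal(nrow(a$cohort), 500L)
  expect_equal(nrow(a$latents), 500L)
  expect_setequal(a$cohort$id, a$latents$id)
  # a different seed gives a different cohort
  c2 <- simulate_model_building_cohort(generative_config(n_participants = 500L,
                                                         seed = 2L))
  expect_false(identical(a$cohort$memory, c2$cohort$memory))
})

test_that("generated columns respect their legal ranges", {
  sim <- small_building()
  co <- sim$cohort
  expect_true(all(co$screener >= 0 & co$screener <= 30))
  expect_true(all(co$word_reading >= 0 & co$word_reading <= 45))
  expect_true(all(co$depression >= 0 & co$depression <= 15))
  expect_true(all(co$cdr_memory %in% c(0, 0.5, 1, 2, 3)))
  expect_true(all(co$cdr_sob >= 0))
  expect_true(all(co$ecog_informant_total >= 1 & co$ecog_informant_total <= 4))
  expect_true(all(co$self_memory_concern %in% c(0, 1)))
  expect_true(all(co$height > 0 & co$weight > 0 & co$waist > 0 & co$hip > 0))
  expect_true(all(co$dbp > 0 & co$sbp >= co$dbp & co$heart_rate > 0))
})

test_that("invalid configurations fail naming the offending field", {
  expect_error(generative_config(race_ethnicity_probs =
                                   c(black_aa = 0.5, hispanic = 0.6, white = 0.1)),
               "race_ethnicity_probs")
  expect_error(generative_config(sex_prob = 1.4), "sex_prob")
  expect_error(generative_config(atrophy_rate_sd = -1), "atrophy_rate_sd")
  expect_error(generative_config(n_visits = 1L), "n_visits")
  expect_error(generative_config(visit_times = c(0, 2, 1)), "visit_times")
})

test_that("zero reserve variance collapses the latent and leaves only noise", {
  cfg <- generative_config(n_participants = 20000L, seed = 3L, reserve_sd = 0)
  sim <- simulate_model_building_cohort(cfg)
  expect_equal(stats::var(sim$latents$reserve), 0)
  X <- rri_design_matrix(sim$cohort)
  res <- stats::lm.fit(X, sim$cohort$memory)$residuals
  # residual variance after regressing on the literal generators ~ noise only
  expect_lt(abs(stats::sd(res) - cfg$noise_sds[["memory"]]), 0.01)
})

test_that("reserve dominates the memory residual as the generative equations imply", {
  cfg <- generative_config(n_participants = 100000L, seed = 4L)
  sim <- simulate_model_building_cohort(cfg)
  X <- rri_design_matrix(sim$cohort)
  res <- stats::lm.fit(X, sim$cohort$memory)$residuals
  # closed-form partial correlation of R with memory given the generators
  expected <- cfg$reserve_sd / sqrt(cfg$reserve_sd^2 + cfg$noise_sds[["memory"]]^2)
  expect_gte(stats::cor(sim$latents$reserve, res), 0.9 * expected)
})

test_that("marginal distributions are calibrated to the configured values", {
  n <- 100000L
  # screener mean placed mid-scale so rounding/clamping is non-binding and the
  # configured location propagates unchanged
  cfg <- generative_config(n_participants = n, seed = 5L, screener_mean = 15)
  sim <- simulate_model_building_cohort(cfg)
  co <- sim$cohort
  se <- function(x) stats::sd(x) / sqrt(n)
  expect_lt(abs(mean(co$age) - cfg$age_mean), 3 * se(co$age))
  expect_lt(abs(stats::sd(co$age) - cfg$age_sd), 3 * cfg$age_sd / sqrt(2 * n))
  # rounding to integers adds variance 1/12 but leaves the mean unchanged
  expect_lt(abs(mean(co$education) - cfg$educ_mean), 3 * se(co$education) + 0.01)
  expect_lt(abs(stats::sd(co$education) - sqrt(cfg$educ_sd^2 + 1 / 12)),
            3 * cfg$educ_sd / sqrt(2 * n) + 0.01)
  expect_lt(abs(mean(co$screener) - cfg$screener_mean), 3 * se(co$screener) + 0.01)
  expect_lt(abs(mean(co$sex) - cfg$sex_prob), 3 * se(co$sex))
  expect_lt(abs(mean(co$black_aa) - 0.143), 3 * se(co$black_aa))
})

test_that("regressing memory on its literal generators recovers the coefficients", {
  cfg <- generative_config(n_participants = 100000L, seed = 6L)
  sim <- simulate_model_building_cohort(cfg)
  d <- cbind(sim$cohort, reserve = sim$latents$reserve)
  fit <- stats::lm(memory ~ gm_signature + log_wmh + sex + black_aa + hispanic +
                     prior_exposure * spanish + offset(reserve), data = d)
  sm <- summary(fit)$coefficients
  truth <- cfg$memory_coeffs
  map <- c(gm_signature = "gm_signature", log_wmh = "log_wmh", sex = "sex",
           black_aa = "black_aa", hispanic = "hispanic",
           prior_exposure = "prior_exposure", spanish = "spanish",
           prior_exposure_x_spanish = "prior_exposure:spanish")
  for (nm in names(map)) {
    expect_lt(abs(sm[map[[nm]], "Estimate"] - truth[[nm]]),
              3 * sm[map[[nm]], "Std. Error"], label = nm)
  }
})

test_that("validation cohort has sound longitudinal structure", {
  cfg <- generative_config(n_participants = 300L, seed = 7L)
  v <- simulate_validation_cohort(cfg)
  lg <- v$longitudinal
  expect_equal(nrow(lg), 300L * cfg$n_visits)
  expect_true(all(lg$gm_change[lg$time == 0] == 0))
  expect_true(all(tapply(lg$time, lg$id, function(t) !is.unsorted(t))))
  # forced-missing features are entirely missing in the emitted cohort table
  expect_true(all(is.na(v$cohort$waist)))
  expect_true(all(is.na(v$cohort$hip)))
  expect_false(anyNA(v$cohort$screener))
})

test_that("positive moderation means less decline per unit grey-matter loss at high reserve", {
  cfg <- generative_config(n_participants = 4000L, seed = 8L,
                           ranef_sd_intercept = 0, ranef_sd_slope = 0)
  v <- simulate_validation_cohort(cfg)
  lg <- v$longitudinal
  r <- v$latents$reserve[match(lg$id, v$latents$id)]
  top <- r >= stats::quantile(r, 0.9)
  bottom <- r <= stats::quantile(r, 0.1)
  slope <- function(sel) {
    stats::coef(stats::lm(ef ~ gm_change + time + gm_baseline,
                          data = lg[sel, ]))[["gm_change"]]
  }
  # gm_change < 0 under atrophy; a smaller positive coefficient means less
  # executive-function loss for the same volume loss
  expect_lt(abs(slope(top)), abs(slope(bottom)))
})

test_that("null_config only zeroes the moderation coefficient and is idempotent", {
  cfg <- generative_config(n_participants = 50L, seed = 9L)
  nc <- null_config(cfg)
  expect_equal(nc$moderation_theta, 0)
  nc2 <- nc; nc2$moderation_theta <- cfg$moderation_theta
  expect_identical(unclass(nc2), unclass(cfg))
  expect_identical(null_config(nc), nc)
})

test_that("under the null the reserve-by-change interaction vanishes at large n", {
  cfg <- null_config(generative_config(n_participants = 20000L, seed = 10L,
                                       n_visits = 3L))
  v <- simulate_validation_cohort(cfg)
  lg <- v$longitudinal
  lg$reserve <- v$latents$reserve[match(lg$id, v$latents$id)]
  # include the true nonzero terms (reserve main effects, intercept
  # moderation) so the only tested coefficient is the genuinely null one
  fit <- stats::lm(ef ~ gm_baseline * reserve + gm_change * reserve +
                     time * reserve, data = lg)
  # cluster-robust SE: repeated visits per participant are not independent
  se_cl <- sqrt(diag(sandwich::vcovCL(fit, cluster = lg$id)))
  expect_lt(abs(stats::coef(fit)[["reserve:gm_change"]]),
            3 * se_cl[["reserve:gm_change"]])
})

test_that("cohort tables round-trip through CSV", {
  v <- simulate_validation_cohort(generative_config(n_participants = 40L, seed = 11L))
  dir <- withr::local_tempdir()
  paths <- write_cohort(v, dir)
  expect_setequal(basename(paths),
                  c("cohort.csv", "longitudinal.csv", "latents.csv"))
  back <- utils::read.csv(file.path(dir, "longitudinal.csv"))
  expect_equal(nrow(back), nrow(v$longitudinal))
  expect_equal(back$ef, v$longitudinal$ef, tolerance = 1e-12)
})
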