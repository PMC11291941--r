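#' Configuration for synthetic cognitive-ageing cohorts
#'
#' Builds and validates the generative configuration used by
#' [simulate_model_building_cohort()] and [simulate_validation_cohort()].
#' The generator emulates a cross-sectional cognitive-ageing cohort in which a
#' standardized episodic memory composite is produced by brain variables
#' (a grey-matter signature and log white-matter hyperintensity volume),
#' demographics, test-exposure terms, and a latent reserve residual \eqn{R};
#' clinical features (screener, word reading, depression, informant ratings,
#' vitals, anthropometrics) are linear-Gaussian functions of \eqn{R}, a
#' continuous disease-severity latent, and demographics, clamped/rounded into
#' their legal ranges. The longitudinal phase generates executive-function
#' trajectories whose dependence on grey-matter change is attenuated by
#' \eqn{R} (coefficient `moderation_theta`).
#'
#' @param n_participants Number of participants.
#' @param seed Integer RNG seed; simulation is bit-reproducible given the
#'   config (the seed lives in the config so a config fully determines a cohort).
#' @param age_mean,age_sd Age distribution (years).
#' @param educ_mean,educ_sd Years-of-education distribution. The reserve
#'   loading on education is carved out of `educ_sd` so the marginal SD equals
#'   the configured value.
#' @param sex_prob Probability of male sex (coded 1).
#' @param race_ethnicity_probs Named simplex over `black_aa`, `hispanic`,
#'   `white`; must sum to 1.
#' @param spanish_prob,prior_exposure_prob Probabilities of Spanish-language
#'   test administration and prior test exposure.
#' @param reserve_sd SD of the latent reserve residual \eqn{R} (memory SD units).
#' @param reserve_loadings Named vector: effect of one unit of \eqn{R} on each
#'   clinical feature (in that feature's own units; `severity` is the loading
#'   on the latent disease-severity score, `self_memory_concern` acts on the
#'   logit scale).
#' @param brain_coeffs Effects of standardized age and disease stage on the
#'   grey-matter signature and logWMH.
#' @param memory_coeffs Generative coefficients of the memory equation
#'   (brain, demographic, exposure and exposure-by-Spanish terms).
#' @param noise_sds Named per-variable residual SDs.
#' @param screener_mean Latent mean of the 0-30 cognitive screener before
#'   rounding/clamping.
#' @param atrophy_rate_mean,atrophy_rate_sd Mean and SD of the annual
#'   grey-matter atrophy rate (SD units per year).
#' @param atrophy_stage_slope Linear dependence of atrophy rate on disease stage.
#' @param n_visits,visit_interval Default visit schedule: baseline plus
#'   `n_visits - 1` follow-ups spaced `visit_interval` years apart.
#' @param visit_times Optional explicit non-decreasing visit-time vector
#'   (years); overrides `n_visits`/`visit_interval`.
#' @param ef_coeffs Fixed effects of the longitudinal executive-function model
#'   (see [simulate_validation_cohort()]).
#' @param ranef_sd_intercept,ranef_sd_slope,ranef_cor Random intercept/slope
#'   SDs and their correlation.
#' @param moderation_theta Coefficient scaling how \eqn{R} attenuates the
#'   effect of grey-matter change on executive function.
#' @param missing_feature_list Cohort columns forced entirely missing in the
#'   validation cohort (emulating features unavailable in an external sample).
#' @return A validated list of class `generative_config`.
#' @export
generative_config <- function(n_participants = 1665L,
                              seed = 1L,
                              age_mean = 74.3, age_sd = 7.5,
                              educ_mean = 14.6, educ_sd = 4.1,
                              sex_prob = 0.47,
                              race_ethnicity_probs = c(black_aa = 0.143,
                                                       hispanic = 0.142,
                                                       white = 0.715),
                              spanish_prob = 0.12,
                              prior_exposure_prob = 0.111,
                              reserve_sd = 0.8,
                              reserve_loadings = c(education = 1.5,
                                                   word_reading = 4.5,
                                                   screener = 1.5,
                                                   depression = -0.4,
                                                   severity = -0.5,
                                                   informant_severity = -0.6,
                                                   self_memory_concern = -0.5,
                                                   dbp = 0.5,
                                                   heart_rate = -0.5,
                                                   height = 0.004,
                                                   bmi = 0.3),
                              brain_coeffs = c(gm_age = -0.35, gm_stage = -0.55,
                                               wmh_age = 0.40, wmh_stage = 0.30),
                              memory_coeffs = c(intercept = 0,
                                                gm_signature = 0.45,
                                                log_wmh = -0.15,
                                                sex = -0.15,
                                                black_aa = -0.25,
                                                hispanic = -0.20,
                                                prior_exposure = 0.25,
                                                spanish = -0.10,
                                                prior_exposure_x_spanish = 0.20),
                              noise_sds = c(memory = 0.35,
                                            gm_signature = 0.55,
                                            log_wmh = 0.80,
                                            word_reading = 6,
                                            screener = 1.8,
                                            depression = 1.6,
                                            severity = 0.5,
                                            dbp = 10,
                                            pulse_pressure = 15,
                                            heart_rate = 10,
                                            height = 0.075,
                                            bmi = 4.8,
                                            waist = 6,
                                            hip = 5,
                                            ef = 0.25),
                              screener_mean = 26.5,
                              atrophy_rate_mean = -0.10,
                              atrophy_rate_sd = 0.04,
                              atrophy_stage_slope = -0.03,
                              n_visits = 4L, visit_interval = 1,
                              visit_times = NULL,
                              ef_coeffs = c(intercept = 0,
                                            age0 = -0.015,
                                            educ = 0.03,
                                            sex = -0.05,
                                            word_reading = 0.012,
                                            gm_baseline = 0.35,
                                            gm_change = 0.80,
                                            time = -0.06,
                                            reserve = 0.35,
                                            reserve_x_time = 0.04,
                                            gm_baseline_x_reserve = 0.20,
                                            gm_baseline_x_reserve_x_time = 0),
                              ranef_sd_intercept = 0.45,
                              ranef_sd_slope = 0.08,
                              ranef_cor = -0.2,
                              moderation_theta = 1.0,
                              missing_feature_list = c("waist", "hip")) {
  cfg <- as.list(environment())
  validate_generative_config(cfg)
  class(cfg) <- "generative_config"
  cfg
}

validate_generative_config <- function(cfg) {
  chk_prob <- function(field) {
    v <- cfg[[field]]
    if (!is.numeric(v) || any(v < 0) || any(v > 1))
      stop_config(field, "must be a probability in [0, 1]")
  }
  for (f in c("sex_prob", "spanish_prob", "prior_exposure_prob")) chk_prob(f)
  rp <- cfg$race_ethnicity_probs
  if (!all(c("black_aa", "hispanic", "white") %in% names(rp)))
    stop_config("race_ethnicity_probs", "must name black_aa, hispanic, white")
  if (any(rp < 0) || abs(sum(rp) - 1) > 1e-12)
    stop_config("race_ethnicity_probs", "must be a simplex summing to 1")
  for (f in c("age_sd", "educ_sd", "reserve_sd", "atrophy_rate_sd",
              "ranef_sd_intercept", "ranef_sd_slope")) {
    if (cfg[[f]] < 0) stop_config(f, "must be a non-negative SD")
  }
  if (any(cfg$noise_sds < 0)) stop_config("noise_sds", "all SDs must be >= 0")
  if (cfg$n_participants < 1) stop_config("n_participants", "must be >= 1")
  if (is.null(cfg$visit_times) && cfg$n_visits < 2)
    stop_config("n_visits", "must be >= 2 (slope unidentifiable otherwise)")
  if (!is.null(cfg$visit_times)) {
    if (length(cfg$visit_times) < 2 || is.unsorted(cfg$visit_times) ||
        cfg$visit_times[1] != 0)
      stop_config("visit_times", "must be non-decreasing, start at 0, length >= 2")
  }
  if (abs(cfg$ranef_cor) > 1) stop_config("ranef_cor", "must be in [-1, 1]")
  edu_load_var <- (cfg$reserve_loadings[["education"]] * cfg$reserve_sd)^2
  if (edu_load_var > cfg$educ_sd^2)
    stop_config("educ_sd", "smaller than the education variance implied by reserve_loadings")
  invisible(cfg)
}

#' Null configuration for type-I-error studies
#'
#' Returns the same configuration with `moderation_theta` set to 0 (so
#' grey-matter change effects on executive function are not moderated by the
#' latent reserve) and everything else untouched. Idempotent.
#'
#' @param config A `generative_config`.
#' @return A `generative_config` identical to `config` except `moderation_theta = 0`.
#' @export
null_config <- function(config) {
  stopifnot(inherits(config, "generative_config"))
  config$moderation_theta <- 0
  config
}

# Cross-sectional draws shared by both phases. Returns the cohort data frame
# plus the latent quantities needed downstream.
simulate_cross_section <- function(config) {
  n <- config$n_participants
  ns <- config$noise_sds
  ld <- config$reserve_loadings

  age <- stats::rnorm(n, config$age_mean, config$age_sd)
  z_age <- (age - config$age_mean) / config$age_sd
  sex <- stats::rbinom(n, 1, config$sex_prob)
  race <- sample(c("black_aa", "hispanic", "white"), n, replace = TRUE,
                 prob = config$race_ethnicity_probs[c("black_aa", "hispanic", "white")])
  black_aa <- as.integer(race == "black_aa")
  hispanic <- as.integer(race == "hispanic")
  spanish <- stats::rbinom(n, 1, config$spanish_prob)
  prior_exposure <- stats::rbinom(n, 1, config$prior_exposure_prob)

  stage <- stats::rnorm(n)                       # continuous disease severity
  reserve <- stats::rnorm(n, 0, config$reserve_sd)

  bc <- config$brain_coeffs
  gm <- bc[["gm_age"]] * z_age + bc[["gm_stage"]] * stage +
    stats::rnorm(n, 0, ns[["gm_signature"]])
  wmh <- bc[["wmh_age"]] * z_age + bc[["wmh_stage"]] * stage +
    stats::rnorm(n, 0, ns[["log_wmh"]])

  mc <- config$memory_coeffs
  memory <- mc[["intercept"]] + mc[["gm_signature"]] * gm + mc[["log_wmh"]] * wmh +
    mc[["sex"]] * sex + mc[["black_aa"]] * black_aa + mc[["hispanic"]] * hispanic +
    mc[["prior_exposure"]] * prior_exposure + mc[["spanish"]] * spanish +
    mc[["prior_exposure_x_spanish"]] * prior_exposure * spanish +
    reserve + stats::rnorm(n, 0, ns[["memory"]])

  # education: reserve loading carved out of the configured marginal SD
  edu_noise_sd <- sqrt(config$educ_sd^2 - (ld[["education"]] * config$reserve_sd)^2)
  education <- round_half_up(config$educ_mean + ld[["education"]] * reserve +
                               stats::rnorm(n, 0, edu_noise_sd))
  education <- clamp(education, 0, 26)

  # severity score seen by raters/tests: disease stage minus reserve protection
  severity <- stage + ld[["severity"]] * reserve + stats::rnorm(n, 0, ns[["severity"]])

  screener <- clamp(round_half_up(config$screener_mean + ld[["screener"]] * reserve -
                                    2.0 * severity + stats::rnorm(n, 0, ns[["screener"]])),
                    0, 30)
  word_reading <- clamp(round_half_up(31 + ld[["word_reading"]] * reserve +
                                        0.5 * (education - config$educ_mean) +
                                        stats::rnorm(n, 0, ns[["word_reading"]])),
                        0, 45)
  depression <- clamp(round_half_up(1.7 + ld[["depression"]] * reserve +
                                      0.5 * severity + stats::rnorm(n, 0, ns[["depression"]])),
                      0, 15)

  # informant-rated severity carries additional reserve information beyond the
  # severity channel shared with the performance tests
  sev_inf <- severity + ld[["informant_severity"]] * reserve +
    stats::rnorm(n, 0, 0.3)
  cdr_sob <- clamp(round(0.8 + 1.3 * sev_inf + stats::rnorm(n, 0, 0.8), 1), 0, 18)
  cdr_memory <- c(0, 0.5, 1, 2, 3)[findInterval(sev_inf, c(-0.2, 0.9, 2.3, 3.4)) + 1L]
  ecog_total <- clamp(1 + 3 * stats::plogis(0.9 * sev_inf - 0.9), 1, 4)
  ecog_memory <- clamp(1 + 3 * stats::plogis(0.9 * sev_inf - 0.55), 1, 4)
  concern <- stats::rbinom(n, 1, stats::plogis(0.8 + 0.6 * severity +
                                                 ld[["self_memory_concern"]] * reserve))

  dbp <- pmax(stats::rnorm(n, 74.3 + ld[["dbp"]] * reserve, ns[["dbp"]]), 35)
  pulse_pressure <- pmax(stats::rnorm(n, 64.7 + 1.5 * stage, ns[["pulse_pressure"]]), 5)
  sbp <- dbp + pulse_pressure
  heart_rate <- pmax(stats::rnorm(n, 66.6 + ld[["heart_rate"]] * reserve,
                                  ns[["heart_rate"]]), 30)
  height <- clamp(1.60 + 0.13 * sex + ld[["height"]] * reserve +
                    stats::rnorm(n, 0, ns[["height"]]), 1.30, 2.10)
  bmi <- clamp(27.5 + ld[["bmi"]] * reserve + stats::rnorm(n, 0, ns[["bmi"]]), 15, 55)
  weight <- bmi * height^2
  waist <- pmax(97 + 2.3 * (bmi - 27.5) + 3 * sex + stats::rnorm(n, 0, ns[["waist"]]), 50)
  hip <- pmax(104 + 2.0 * (bmi - 27.5) - 2 * sex + stats::rnorm(n, 0, ns[["hip"]]), 60)

  atrophy <- config$atrophy_rate_mean + config$atrophy_stage_slope * stage +
    stats::rnorm(n, 0, config$atrophy_rate_sd)

  cohort <- data.frame(
    id = seq_len(n),
    age = age, education = education, sex = sex,
    black_aa = black_aa, hispanic = hispanic,
    spanish = spanish, prior_exposure = prior_exposure,
    gm_signature = gm, log_wmh = wmh, memory = memory,
    sbp = sbp, dbp = dbp, heart_rate = heart_rate,
    height = height, weight = weight, waist = waist, hip = hip,
    screener = screener, word_reading = word_reading, depression = depression,
    cdr_sob = cdr_sob, cdr_memory = cdr_memory,
    ecog_informant_total = ecog_total, ecog_informant_memory = ecog_memory,
    self_memory_concern = concern
  )
  latents <- data.frame(id = seq_len(n), reserve = reserve,
                        gm_baseline = gm, gm_slope = atrophy,
                        disease_stage = stage)
  list(cohort = cohort, latents = latents)
}

#' Simulate a model-building cohort with known latent reserve
#'
#' Generates one row per participant. Memory is generated as
#' `memory = b_gm * gm + b_wmh * logwmh + demographic terms + exposure terms + R + e`
#' with `R ~ Normal(0, reserve_sd^2)`; clinical features are generated from
#' `R`, the disease-severity latent, and noise according to
#' `reserve_loadings`. Deterministic given the config (which carries the seed).
#'
#' @param config A [generative_config()].
#' @return A list with elements `cohort` (data frame, one row per participant)
#'   and `latents` (data frame of the true per-participant latent quantities:
#'   `reserve`, `gm_baseline`, `gm_slope`, `disease_stage`).
#' @export
simulate_model_building_cohort <- function(config) {
  stopifnot(inherits(config, "generative_config"))
  validate_generative_config(config)
  with_seed(derive_seed(config$seed, "building"), {
    out <- simulate_cross_section(config)
    out$cohort$id <- sprintf("B%05d", out$cohort$id)
    out$latents$id <- out$cohort$id
    out
  })
}

#' Simulate an external-validation cohort with longitudinal trajectories
#'
#' Generates the cross-sectional clinical table (with any
#' `missing_feature_list` columns forced missing, emulating features that are
#' unavailable in an external sample) plus a participant-visit table of
#' executive-function trajectories. At visit time `t`,
#' \deqn{ef = \beta_0 + covariates + \beta_b gm_b + (\beta_\Delta - \theta R) gm_\Delta
#'   + \beta_R R + \beta_{Rt} R t + \beta_{bR} gm_b R + \beta_t t + u_0 + u_1 t + e}
#' with correlated random intercepts/slopes and `gm_change = atrophy_rate * t`
#' (exactly 0 at baseline). A positive `moderation_theta` therefore
#' *attenuates* the executive-function cost of grey-matter loss for
#' high-reserve participants: at `R = beta_Delta / theta` the brain-change
#' effect is fully neutralized, matching the near-flat high-reserve
#' trajectories this generator is meant to emulate.
#'
#' @param config A [generative_config()] with `n_visits >= 2` (or explicit
#'   `visit_times`).
#' @return A list with `cohort`, `longitudinal`, and `latents` data frames.
#' @export
simulate_validation_cohort <- function(config) {
  stopifnot(inherits(config, "generative_config"))
  validate_generative_config(config)
  with_seed(derive_seed(config$seed, "validation"), {
    out <- simulate_cross_section(config)
    n <- config$n_participants
    times <- config$visit_times %||%
      (seq_len(config$n_visits) - 1) * config$visit_interval
    nv <- length(times)
    ec <- config$ef_coeffs
    reserve <- out$latents$reserve
    gm_b <- out$latents$gm_baseline
    rate <- out$latents$gm_slope

    sds <- c(config$ranef_sd_intercept, config$ranef_sd_slope)
    cov_u <- config$ranef_cor * prod(sds)
    sigma_u <- matrix(c(sds[1]^2, cov_u, cov_u, sds[2]^2), 2, 2)
    L <- chol(sigma_u + diag(1e-12, 2))
    u <- matrix(stats::rnorm(2 * n), n, 2) %*% L

    idx <- rep(seq_len(n), each = nv)
    tt <- rep(times, n)
    gm_change <- rate[idx] * tt
    ef <- ec[["intercept"]] +
      ec[["age0"]] * (out$cohort$age[idx] - 70) +
      ec[["educ"]] * (out$cohort$education[idx] - 12) +
      ec[["sex"]] * out$cohort$sex[idx] +
      ec[["word_reading"]] * (out$cohort$word_reading[idx] - 31) +
      ec[["gm_baseline"]] * gm_b[idx] +
      (ec[["gm_change"]] - config$moderation_theta * reserve[idx]) * gm_change +
      ec[["time"]] * tt +
      ec[["reserve"]] * reserve[idx] +
      ec[["reserve_x_time"]] * reserve[idx] * tt +
      ec[["gm_baseline_x_reserve"]] * gm_b[idx] * reserve[idx] +
      ec[["gm_baseline_x_reserve_x_time"]] * gm_b[idx] * reserve[idx] * tt +
      u[idx, 1] + u[idx, 2] * tt +
      stats::rnorm(n * nv, 0, config$noise_sds[["ef"]])

    out$cohort$id <- sprintf("V%05d", out$cohort$id)
    out$latents$id <- out$cohort$id
    longitudinal <- data.frame(
      id = out$cohort$id[idx],
      time = tt,
      ef = ef,
      gm_baseline = gm_b[idx],
      gm_change = gm_change,
      age0 = out$cohort$age[idx],
      educ = out$cohort$education[idx],
      sex = out$cohort$sex[idx],
      word_reading = out$cohort$word_reading[idx]
    )
    for (col in config$missing_feature_list) {
      if (col %in% names(out$cohort)) out$cohort[[col]] <- NA_real_
    }
    list(cohort = out$cohort, longitudinal = longitudinal, latents = out$latents)
  })
}

#' Write a simulated cohort to CSV files
#'
#' Writes `cohort.csv`, `latents.csv`, and (when present) `longitudinal.csv`
#' under `dir`, with missing values rendered as empty cells.
#'
#' @param sim Result of [simulate_model_building_cohort()] or
#'   [simulate_validation_cohort()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_cohort <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  for (nm in intersect(c("cohort", "longitudinal", "latents"), names(sim))) {
    p <- file.path(dir, paste0(nm, ".csv"))
    utils::write.csv(sim[[nm]], p, row.names = FALSE, na = "")
    paths <- c(paths, p)
  }
  invisible(paths)
}
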