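#' Tier specification for surrogate predictors
#'
#' The three predictor tiers form a strict nesting. `minimal` holds basic
#' clinical measurements obtainable at any out-patient visit (demographics,
#' vitals, anthropometric indices, a single self-reported memory concern);
#' `extended` adds a cognitive screener (MMSE-equivalent), word reading, and
#' depression scores; `full` adds informant-based dementia-severity and
#' everyday-cognition ratings.
#'
#' @param tier One of `"minimal"`, `"extended"`, `"full"`.
#' @return A list of class `tier_spec` with `tier` and the ordered
#'   `feature_names`.
#' @export
tier_spec <- function(tier = c("minimal", "extended", "full")) {
  tier <- match.arg(tier)
  minimal <- c("age", "education", "sex", "dbp", "pulse_pressure", "heart_rate",
               "height", "bmi", "absi", "hip_index", "waist_hip_index",
               "self_memory_concern")
  extended <- c(minimal, "screener_mmse_equiv", "word_reading_45", "depression")
  full <- c(extended, "cdr_sob", "cdr_memory", "ecog_informant_total",
            "ecog_informant_memory")
  structure(list(tier = tier,
                 feature_names = switch(tier, minimal = minimal,
                                        extended = extended, full = full)),
            class = "tier_spec")
}

#' Body mass index
#'
#' @param weight Weight in kg.
#' @param height Height in m.
#' @return BMI in kg/m^2. `NA` inputs propagate to `NA`.
#' @export
compute_bmi <- function(weight, height) {
  if (any(weight <= 0, na.rm = TRUE) || any(height <= 0, na.rm = TRUE))
    stop("weight and height must be positive")
  weight / height^2
}

#' Pulse pressure
#'
#' @param sbp,dbp Systolic and diastolic blood pressure (mmHg); `sbp >= dbp`.
#' @return `sbp - dbp` in mmHg.
#' @export
compute_pulse_pressure <- function(sbp, dbp) {
  if (any(sbp < dbp, na.rm = TRUE))
    stop("systolic pressure must be >= diastolic pressure")
  sbp - dbp
}

#' Allometric anthropometric index specification
#'
#' Defines a power-law index `scale * measurement * height^height_exp *
#' base^base_exp`, where `base` is BMI or weight. Defaults:
#' * ABSI (body shape index): waist (m) scaled by `BMI^(-2/3) * height^(-1/2)`,
#'   i.e. waist circumference made independent of height and BMI.
#' * Hip index: hip circumference scaled by `height^0.310 * weight^(-0.482)`.
#' * Waist-hip index: the raw waist/hip ratio (exponents 0).
#' The exact constants used in published normed versions of these indices
#' include unstated scale factors, so `scale` (and every exponent) is exposed
#' rather than hard-coded.
#'
#' @param name One of `"absi"`, `"hip_index"`, `"waist_hip_index"`.
#' @param height_exp,base_exp Exponents on height (m) and on the base quantity.
#' @param base `"bmi"` or `"weight"`.
#' @param scale Positive multiplier.
#' @return A list of class `allometric_spec`.
#' @export
allometric_spec <- function(name = c("absi", "hip_index", "waist_hip_index"),
                            height_exp = NULL, base_exp = NULL,
                            base = NULL, scale = 1) {
  name <- match.arg(name)
  defaults <- switch(name,
    absi = list(height_exp = -0.5, base_exp = -2 / 3, base = "bmi"),
    hip_index = list(height_exp = 0.310, base_exp = -0.482, base = "weight"),
    waist_hip_index = list(height_exp = 0, base_exp = 0, base = "bmi"))
  spec <- list(name = name,
               height_exp = height_exp %||% defaults$height_exp,
               base_exp = base_exp %||% defaults$base_exp,
               base = match.arg(base %||% defaults$base, c("bmi", "weight")),
               scale = scale)
  if (spec$scale <= 0) stop("scale must be > 0")
  structure(spec, class = "allometric_spec")
}

#' Compute an allometric anthropometric index
#'
#' @param measurement The circumference measurement (for the waist-hip index,
#'   the waist/hip ratio); units must match the convention of `spec`
#'   (ABSI expects waist in metres).
#' @param height Height in m.
#' @param base_value BMI (kg/m^2) or weight (kg), per `spec$base`.
#' @param spec An [allometric_spec()].
#' @return `scale * measurement * height^height_exp * base_value^base_exp`.
#'   `NA` inputs propagate.
#' @export
compute_allometric_index <- function(measurement, height, base_value, spec) {
  stopifnot(inherits(spec, "allometric_spec"))
  if (any(measurement <= 0, na.rm = TRUE) || any(height <= 0, na.rm = TRUE) ||
      any(base_value <= 0, na.rm = TRUE))
    stop("allometric index inputs must be positive")
  spec$scale * measurement * height^spec$height_exp * base_value^spec$base_exp
}

#' Default MoCA-to-MMSE crosswalk table
#'
#' A 31-row lookup covering MoCA 0-30. The default is the identity mapping;
#' a published crosswalk can be supplied as a CSV with columns `input` and
#' `output` via [load_crosswalk()].
#'
#' @return Data frame with integer columns `input` (0-30) and `output`.
#' @export
default_crosswalk <- function() data.frame(input = 0:30, output = 0:30)

#' Load and validate a score crosswalk table
#'
#' @param path CSV file with columns `input` and `output`.
#' @param inputs Required input domain (default 0:30).
#' @param range Legal output range.
#' @return Validated crosswalk data frame.
#' @export
load_crosswalk <- function(path, inputs = 0:30, range = c(0, 30)) {
  tab <- utils::read.csv(path)
  validate_crosswalk(tab, inputs, range)
}

validate_crosswalk <- function(tab, inputs = 0:30, range = c(0, 30)) {
  if (!all(c("input", "output") %in% names(tab)))
    stop("crosswalk must have columns 'input' and 'output'")
  if (!setequal(tab$input, inputs))
    stop("crosswalk must cover every input score exactly once")
  tab <- tab[order(tab$input), , drop = FALSE]
  if (is.unsorted(tab$output))
    stop("crosswalk outputs must be monotone non-decreasing in the input")
  if (any(tab$output < range[1] | tab$output > range[2]))
    stop(sprintf("crosswalk outputs must lie in [%s, %s]", range[1], range[2]))
  tab
}

#' Convert MoCA scores to MMSE equivalents
#'
#' @param moca Integer MoCA scores in 0-30 (`NA` allowed, propagates).
#' @param crosswalk Crosswalk table (see [default_crosswalk()]).
#' @return MMSE-equivalent scores in 0-30.
#' @export
convert_moca_to_mmse <- function(moca, crosswalk = default_crosswalk()) {
  crosswalk <- validate_crosswalk(crosswalk)
  ok <- is.na(moca) | (moca == round(moca) & moca >= 0 & moca <= 30)
  if (!all(ok)) stop("MoCA scores must be integers in [0, 30]")
  crosswalk$output[match(moca, crosswalk$input)]
}

#' Convert 50-item word-reading scores to 45-item equivalents
#'
#' Defaults to proportional rescaling with round-half-up,
#' `round(score50 * 45/50)`; an alternative monotone mapping (a data frame with
#' columns `input` covering 0-50 and `output` in 0-45) can be injected.
#'
#' @param score50 Scores in 0-50 (`NA` propagates).
#' @param mapping Optional lookup table replacing the proportional default.
#' @return Scores in 0-45.
#' @export
convert_amnart50_to_45 <- function(score50, mapping = NULL) {
  ok <- is.na(score50) | (score50 >= 0 & score50 <= 50)
  if (!all(ok)) stop("50-item scores must lie in [0, 50]")
  if (is.null(mapping)) return(round_half_up(score50 * 45 / 50))
  mapping <- validate_crosswalk(mapping, inputs = 0:50, range = c(0, 45))
  mapping$output[match(score50, mapping$input)]
}

#' Assemble tier-specific feature vectors from a cohort table
#'
#' Computes the derived predictors (pulse pressure, BMI, allometric indices,
#' screener MMSE-equivalent, 45-item word reading) and returns a data frame
#' whose columns are exactly the tier's ordered feature names. Any source
#' column that is absent or missing yields `NA` in the features that depend on
#' it — never an error — so missingness propagates only where it must and can
#' be routed natively by the downstream learner.
#'
#' If the cohort has a `moca` column and `screener` is absent/missing, the
#' screener MMSE-equivalent is obtained through `crosswalk`. A
#' `word_reading_50` column is converted via [convert_amnart50_to_45()] when
#' `word_reading` is absent.
#'
#' @param cohort Data frame of participant records (see
#'   [simulate_model_building_cohort()] for the column dictionary).
#' @param tier A [tier_spec()] or tier name.
#' @param crosswalk MoCA-to-MMSE crosswalk table.
#' @param absi,hip_index,waist_hip_index [allometric_spec()]s for the
#'   anthropometric indices.
#' @return Data frame with attribute `tier`; columns equal
#'   `tier$feature_names`, rows aligned to `cohort`.
#' @export
assemble_features <- function(cohort, tier = tier_spec("full"),
                              crosswalk = default_crosswalk(),
                              absi = allometric_spec("absi"),
                              hip_index = allometric_spec("hip_index"),
                              waist_hip_index = allometric_spec("waist_hip_index")) {
  if (is.character(tier)) tier <- tier_spec(tier)
  stopifnot(inherits(tier, "tier_spec"))
  n <- nrow(cohort)
  col <- function(nm) if (nm %in% names(cohort)) cohort[[nm]] else rep(NA_real_, n)

  height <- col("height")
  weight <- col("weight")
  bmi <- ifelse(!is.na(weight) & !is.na(height) & weight > 0 & height > 0,
                weight / height^2, NA_real_)
  sbp <- col("sbp"); dbp <- col("dbp")
  pp <- ifelse(!is.na(sbp) & !is.na(dbp) & sbp >= dbp, sbp - dbp, NA_real_)
  waist <- col("waist"); hip <- col("hip")

  safe_allo <- function(meas, base_value, spec) {
    ok <- !is.na(meas) & !is.na(height) & !is.na(base_value) &
      meas > 0 & height > 0 & base_value > 0
    out <- rep(NA_real_, n)
    if (any(ok))
      out[ok] <- compute_allometric_index(meas[ok], height[ok], base_value[ok], spec)
    out
  }
  absi_v <- safe_allo(waist / 100, bmi, absi)           # waist in metres
  hi_v <- safe_allo(hip, weight, hip_index)
  whr <- ifelse(!is.na(waist) & !is.na(hip) & hip > 0, waist / hip, NA_real_)
  whi_v <- safe_allo(whr, bmi, waist_hip_index)

  screener <- col("screener")
  if ("moca" %in% names(cohort)) {
    use_moca <- is.na(screener) & !is.na(cohort$moca)
    if (any(use_moca))
      screener[use_moca] <- convert_moca_to_mmse(cohort$moca[use_moca], crosswalk)
  }
  word45 <- col("word_reading")
  if (all(is.na(word45)) && "word_reading_50" %in% names(cohort))
    word45 <- convert_amnart50_to_45(cohort$word_reading_50)

  derived <- list(
    age = col("age"), education = col("education"), sex = col("sex"),
    dbp = dbp, pulse_pressure = pp, heart_rate = col("heart_rate"),
    height = height, bmi = bmi, absi = absi_v, hip_index = hi_v,
    waist_hip_index = whi_v,
    self_memory_concern = as.numeric(col("self_memory_concern") > 0),
    screener_mmse_equiv = screener, word_reading_45 = word45,
    depression = col("depression"), cdr_sob = col("cdr_sob"),
    cdr_memory = col("cdr_memory"),
    ecog_informant_total = col("ecog_informant_total"),
    ecog_informant_memory = col("ecog_informant_memory"))

  out <- as.data.frame(derived[tier$feature_names])
  attr(out, "tier") <- tier
  if ("id" %in% names(cohort)) attr(out, "id") <- cohort$id
  out
}
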