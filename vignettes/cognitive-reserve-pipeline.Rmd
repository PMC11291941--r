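---
title: "Estimating and validating clinical surrogates of residual cognitive reserve"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating and validating clinical surrogates of residual cognitive reserve}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cogreserve)
```

## The problem

Cognitive reserve names the observation that, for the same amount of brain
ageing or pathology, some people's cognition holds up much better than
others'. The residual operationalization defines reserve as what is left of
episodic memory performance after brain structure and demographics have
explained what they can: participants who remember better than their brain
would predict have high reserve. This residual reserve index (RRI) has two
well-known drawbacks — it needs MRI plus a large latent-variable analysis, so
it cannot be produced for an individual patient, and it offers no insight
into *what* makes reserve high.

`cogreserve` implements a complete, testable pipeline around a pragmatic
answer: train a gradient-boosted regression model to predict the RRI from
ordinary clinical variables, and judge the result not by accuracy alone but
by the defining functional property of a reserve measure — its ability to
*moderate* longitudinal brain–cognition associations. Because the real
cohorts behind this design are access-restricted, the package ships a
synthetic-cohort generator with a known latent reserve, so every stage of the
pipeline can be exercised and audited end to end.

## The criterion model

The criterion is a single-indicator linear-Gaussian latent decomposition of a
standardized episodic memory composite \(M\):

\[
M_i = \beta_0 + \beta_{gm}\,GM_i + \beta_{wmh}\,\log WMH_i
  + \boldsymbol{\beta}_d^\top d_i + \boldsymbol{\beta}_e^\top e_i + R_i + \varepsilon_i ,
\qquad R_i \sim N(0, \psi),\; \varepsilon_i \sim N(0, \sigma_m^2),
\]

where \(GM\) is a grey-matter signature volume, \(d\) holds demographic
indicators (sex, Black/African-American, Hispanic/Latinx; White as
reference), and \(e\) holds test-exposure terms (prior exposure, Spanish
administration, and their interaction). Education is deliberately *not*
partialled out: the residual is allowed to share variance with education so
that education can later be compared against other predictors of reserve.

With one indicator and known measurement-error variance \(\sigma_m^2\)
(zero by default), maximum likelihood coincides with ordinary least squares;
`fit_rri()` therefore solves the normal equations exactly and reports
\(\psi\) as the divisor-\(n\) residual variance. `score_rri()` returns
regression-method (posterior-mean) factor scores
\(\hat R_i = \frac{\psi}{\psi + \sigma_m^2}\,r_i\) for raw residual \(r_i\),
standardized to mean 0, SD 1, with determinacy
\(\rho^2 = \psi / (\psi + \sigma_m^2)\). Every quantity has a closed-form
conditional-Gaussian oracle, which the test suite exploits.

`latent_correlation()` reproduces the fixed-parameter convergent-validity
check: with every criterion-model parameter frozen, the single free parameter
is the correlation between the latent residual and a proxy score, estimated
by maximizing the bivariate-normal likelihood (the score equation is a cubic
solved exactly). With variances fixed at divisor-\(n\) sample moments the
zero-error estimate equals the Pearson correlation with the raw residual; in
general it behaves as the disattenuated correlation
\(r_{obs}/\rho\).

## Predictor tiers and derived features

Three nested predictor tiers mirror what different care settings can
collect:

* **Minimal** (12 features): age, education, sex, diastolic pressure, pulse
  pressure, heart rate, height, BMI, three allometric anthropometric indices
  (a body-shape index from waist circumference, a hip index, a waist–hip
  index), and a single self-reported memory concern.
* **Extended** (+3): a 0–30 cognitive screener (MMSE equivalent; MoCA scores
  pass through a configurable 31-row crosswalk), a 0–45 word-reading score
  (50-item versions rescale by `round(score * 45/50)` by default), and a
  0–15 depression score.
* **Full** (+4): informant-based dementia-severity ratings (CDR sum of boxes
  and memory box) and everyday-cognition ratings (informant total and memory
  domain).

The allometric indices are power-law forms
`scale * measurement * height^a * base^b`. Their published normed versions
involve constants that are not reproducible from first principles, so the
exponents and scale are configuration, with defaults
waist(m)·BMI^(−2/3)·height^(−1/2) for the body-shape index,
hip·height^0.310·weight^(−0.482) for the hip index, and the raw waist/hip
ratio for the waist–hip index. `assemble_features()` never throws on missing
data: an absent or missing source column yields `NA` exactly in the features
that depend on it, and the boosted trees route missing values natively.

## The surrogate and its tuning protocol

Surrogates are gradient-boosted tree ensembles (XGBoost) trained on a random
75% of the model-building cohort against the standardized factor scores; the
remaining 25% is held out. Hyperparameters (tree depth 2–8, learning rate
0.01–0.3 on a log scale, minimum child weight 1–20, row/column subsampling
0.5–1, 100–1500 trees, L2 regularization 0.001–10 on a log scale) are tuned
by out-of-fold RMSE over a fixed 10-fold partition of the training set. The
search is surrogate-guided: a space-filling Latin-hypercube design seeds the
log, then a random-forest surrogate fitted to (hyperparameters → CV RMSE)
proposes each next candidate from a fresh hypercube, with 20% random
exploration. The search stops after at most 200 candidates or 100
consecutive candidates without improvement, and always returns the argmin of
the logged candidates; both stopping constants are configuration.

Accuracy is reported as RMSE and Pearson correlation against the criterion
on the held-out quarter, plus the fixed-parameter latent correlation above.
Attribution uses the ensemble's own structure: split-gain importances
(normalized to sum to 1) and path-dependent tree-Shapley values, which
satisfy local accuracy row by row and carry missingness as an explicit
category in the beeswarm export. The path-dependent variant was chosen over
interventional Shapley with a background sample because it is deterministic
and standard for boosted trees; note both the model evaluation and the
Shapley recursion run in single precision, so additivity holds to about
1e-6 on moderately sized ensembles, tighter on small ones.

## External validation: the moderation ladder

Validity as a *reserve* measure is tested in an independent longitudinal
cohort by a sequence of four nested linear mixed models for executive
function, each with correlated random intercepts and time slopes per
participant, estimated by maximum likelihood (not REML, because the stages
differ in fixed effects):

* **E1, covariates only** — time, baseline age (centred at 70), education
  (centred at 12), sex, word reading, each with its time interaction;
  baseline grey matter, grey-matter change, baseline-by-time; and the
  moderation terms of the two comparison proxies (education and word
  reading) so that later stages isolate the tested proxy's increment.
* **E2, no moderation** — adds the proxy and proxy-by-time (2 df).
* **E3, intercept moderation** — adds proxy-by-baseline-grey-matter (1 df).
* **E4, slope moderation** — adds proxy-by-baseline-by-time and
  proxy-by-grey-matter-change (2 df).

Consecutive stages are compared by likelihood-ratio chi-squares on a common
listwise-complete row set. The reported log-likelihood of every fit is
checked against a from-scratch evaluation of the marginal multivariate
normal density (`lmm_loglik_direct()`), and deviance differences that are
negative by more than 1e-6 are treated as optimizer failures rather than
clamped. When the tested proxy is itself one of the comparison covariates
(the education-only and word-reading-only ladders), it is removed from the
baseline stage so the increments stay full rank. `predict_trajectories()`
turns a fitted stage into fixed-effects trajectories for a reference profile
(by default a 70-year-old woman with 12 years of education) across atrophy
rates of −0.05, −0.10 and −0.15 SD/year.

## What the synthetic cohorts emulate

`generative_config()` fixes the study conditions. Demographics match the
descriptive statistics of the cohorts the design targets (age 74.3 ± 7.5,
education 14.6 ± 4.1, 47% male, 14.3% Black/African-American, 14.2%
Hispanic/Latinx, 11.1% prior test exposure; model-building n = 1665,
validation n = 1640). Brain variables load on standardized age and a
continuous disease-severity latent; memory follows the criterion model
literally, with reserve SD 0.8 and residual noise SD 0.35 in standardized
memory units. Clinical features are linear-Gaussian in reserve, severity,
and demographics, then rounded/clamped into their legal ranges — the
pre-clamp structure keeps closed-form oracles available. Ordinal informant
measures (CDR, ECog) arise by monotone transforms and binning of a severity
score; the informant-observed severity carries its own reserve loading
(−0.6), making informant ratings more informative than the screener alone.
That choice, together with loadings of 1.5 (education), 4.5 (word reading),
and 1.5 (screener), yields held-out criterion correlations near 0.25 / 0.55
/ 0.60 for the Minimal / Extended / Full tiers — the qualitative pattern the
pipeline is designed to detect: vitals and anthropometrics weakly
informative, cognitive performance dominant, informant data a further
increment.

Longitudinally, each participant's atrophy rate is
`-0.10 - 0.03 * severity + noise` SD/year over baseline plus annual visits
(4 by default), and executive function follows

\[
EF_{it} = \beta^\top x_i + \beta_b\,GM_i + (\beta_\Delta - \theta R_i)\,\Delta GM_{it}
 + \beta_R R_i + \beta_{Rt} R_i t + \beta_{bR} GM_i R_i
 + \beta_t t + u_{0i} + u_{1i} t + e_{it}.
\]

Positive `moderation_theta` *attenuates* the executive-function cost of
grey-matter loss: with the defaults (\(\beta_\Delta = 0.8, \theta = 1.0\)) a
participant one reserve-SD above average is fully insulated from volume
loss, which reproduces the near-flat high-reserve trajectories the design
expects; beyond that point the linear form mildly overshoots, a known
limitation of the linear interaction. The generator also includes nonzero
reserve main effects and intercept moderation so all three ladder increments
carry true signal; `null_config()` zeroes only `moderation_theta`, making
the E4-vs-E3 test an exact null for type-I-error studies.

What the generator does **not** emulate: item-level test responses, dropout
and mortality, cohort heterogeneity (site effects, scanner differences),
non-Gaussian feature distributions beyond clamping, and time-varying
reserve. Passing tests therefore demonstrate the pipeline's statistical
machinery under a faithful but idealized data-generating process, not
performance on real cohorts.

## Numerical and design choices

* ML residual variance uses divisor *n*, so the least-squares oracle
  equalities in the tests hold to machine precision.
* Missing data: listwise deletion (with logged counts) for the criterion
  model and the ladder — deletion keeps ML exactness and LRT validity on a
  common row set; native tree routing, never imputation, for the surrogate.
* Rank-deficient criterion designs error out naming the collinear columns.
* Singular random-effect fits are refitted with a diagonal covariance and
  flagged; non-converged stages void their ladder comparisons.
* The 75/25 split is simple random (unstratified), matching the protocol it
  reproduces.
* Seeds: every stochastic stage derives its own seed deterministically from
  a single top-level seed, so an experiment is reproducible bit for bit.
* The self-report memory concern is binarized (any affirmative response is
  1); depression enters as a raw 0-15 total.

## Problem sizes used by the test suite

The packaged checks run at desk scale, chosen once: criterion and oracle
checks on cohorts of 500–1665; the type-I-error study uses 500 replicates of
600 participants × 4 visits, fitting only the E3/E4 stages (the smallest
size at which the chi-square reference for the maximum-likelihood ratio
test is accurate — at 250 participants the many between-person interaction
terms leave the test visibly anticonservative); the power
pattern uses one validation cohort of 2000; the tier-ordering experiment
repeats the full model-building phase 10 times at n = 1665 with a
4-candidate, 5-fold tuner over 100–300 trees; the acceptance script runs the
whole pipeline once at n = 1665 / 1640 with a 12-candidate, 10-fold tuner
over 100–600 trees. Larger searches change the tuned constants, not the
qualitative results.

## A worked run

```{r example, eval = FALSE}
cfg <- experiment_config(
  seed = 1L,
  building = generative_config(n_participants = 800L, seed = 1L),
  validation = generative_config(n_participants = 600L, seed = 2L),
  tiers = c("minimal", "extended", "full"),
  tuner = tuner_config(n_folds = 5L, max_iterations = 8L, patience = 8L))
result <- run_experiment(cfg, out_dir = "run1")
writeLines(report_experiment(result))
```

The report tabulates, per tier, the cross-validated, training and held-out
RMSE, held-out and latent correlations, and the four-model ladder with
parameter counts, AIC, BIC, log-likelihoods, deviances, chi-square
increments (with their 2, 1, 2 degrees of freedom) and p-values, followed by
the comparison-proxy ladders and the top of each importance ranking.
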