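# cogreserve

Machine-learning surrogates for residual-based cognitive reserve, with
longitudinal moderation validation.

## The problem

Cognitive reserve is whatever lets some people's cognition withstand brain
ageing and pathology better than others'. The strongest available
operationalization is the **residual reserve index (RRI)**: the residual
variance in episodic memory after brain structure and demographics have been
partialled out in a latent-variable model,

```
memory = b0 + b_gm * GM_signature + b_wmh * logWMH
       + demographics + exposure terms + RRI + error,   RRI ~ N(0, psi)
```

This criterion needs MRI and a large cohort, so it cannot be computed for an
individual patient. `cogreserve` implements the full pipeline that works
around this: it trains tiered gradient-boosted (XGBoost) surrogates of the
RRI from ordinary clinical variables — a **Minimal** tier (demographics,
vitals, anthropometric indices, a self-reported memory concern), an
**Extended** tier (plus cognitive screener, word reading, depression), and a
**Full** tier (plus informant CDR and everyday-cognition ratings) — and then
tests each surrogate's *construct validity*: whether its scores moderate the
effect of grey-matter change on executive-function trajectories in an
independent longitudinal cohort, via a ladder of four nested mixed models
compared by likelihood-ratio tests with degrees of freedom 2 (proxy main
effects), 1 (intercept moderation), and 2 (slope moderation).

Because the cohorts this design targets are access-restricted, the package
includes a first-class synthetic-cohort generator with a known latent
reserve, calibrated so the qualitative findings the pipeline is built to
detect (tier ordering of accuracy, moderation by informative tiers only) are
reproducible and testable end to end. Intended users are biostatisticians
and cognitive-ageing researchers who want to audit, extend, or re-run this
class of analysis.

## A worked example

```r
library(cogreserve)

cfg <- experiment_config(
  seed = 1L,
  building   = generative_config(n_participants = 800L, seed = 1L),
  validation = generative_config(n_participants = 600L, seed = 2L),
  tiers = c("minimal", "extended", "full"),
  tuner = tuner_config(n_folds = 5L, max_iterations = 8L, patience = 8L))
result <- run_experiment(cfg)
writeLines(report_experiment(result))
```

prints (abridged):

```
Criterion: residual variance psi = 0.7320 on n = 800 participants; scored factor scores standardized to mean 0, SD 1.

## Surrogate accuracy

| Tier | CV RMSE | Train RMSE | Held-out RMSE | Held-out r | Latent r (SE) |
|---|---|---|---|---|---|
| minimal | 1.015 | 0.526 | 1.072 | 0.088 | 0.088 (0.070) |
| extended | 0.832 | 0.543 | 0.842 | 0.549 | 0.549 (0.043) |
| full | 0.808 | 0.528 | 0.813 | 0.584 | 0.584 (0.040) |

## Moderation ladder: minimal tier

| Label | Model | # Parameters | AIC | BIC | logLik | Deviance | Dchisq | Ddf | P | Comparison |
|---|---|---|---|---|---|---|---|---|---|---|
| E1 | Covariates Only | 23 | 2594.5 | 2727.6 | -1274.3 | 2548.5 | - | - | - | - |
| E2 | No Moderation | 25 | 2587.1 | 2731.7 | -1268.6 | 2537.1 | 11.41 | 2 | <0.01 | E2 versus E1 |
| E3 | Intercept Moderation | 26 | 2589.1 | 2739.5 | -1268.5 | 2537.1 | 0.04 | 1 | 0.85 | E3 versus E2 |
| E4 | Slope Moderation | 28 | 2591.5 | 2753.4 | -1267.7 | 2535.5 | 1.61 | 2 | 0.45 | E4 versus E3 |

## Moderation ladder: extended tier

| Label | Model | # Parameters | AIC | BIC | logLik | Deviance | Dchisq | Ddf | P | Comparison |
|---|---|---|---|---|---|---|---|---|---|---|
| E1 | Covariates Only | 23 | 2594.5 | 2727.6 | -1274.3 | 2548.5 | - | - | - | - |
| E2 | No Moderation | 25 | 2509.4 | 2654.0 | -1229.7 | 2459.4 | 89.15 | 2 | <0.01 | E2 versus E1 |
| E3 | Intercept Moderation | 26 | 2505.9 | 2656.2 | -1226.9 | 2453.9 | 5.51 | 1 | 0.02 | E3 versus E2 |
| E4 | Slope Moderation | 28 | 2500.7 | 2662.6 | -1222.3 | 2444.7 | 9.21 | 2 | <0.01 | E4 versus E3 |
```

Reading this: the held-out correlation with the criterion rises steeply from
the Minimal tier (r = 0.09 — vitals and anthropometrics alone carry almost
no reserve signal at this cohort size) to the Extended tier (r = 0.55 —
cognitive performance data is what matters), and modestly again for the
Full tier (r = 0.58 — informant ratings add a further increment). In the
external-validation ladders, the Minimal surrogate improves fit only as a
main effect and fails both moderation stages (p = 0.85, p = 0.45), while
the Extended surrogate also moderates the baseline-volume effect on the
executive-function intercept (df = 1) and the effect of grey-matter
*change* on the executive-function *slope* (df = 2, p < 0.01) — the
defining behaviour of a cognitive reserve measure. The education-only
comparison ladder fails the moderation stages on the same data (p = 0.41,
p = 0.46), and larger validation cohorts sharpen all of these contrasts.

Individual stages are exposed as ordinary functions: `fit_rri()` /
`score_rri()` (criterion), `split_train_test()`, `tune_proxy()`,
`fit_final()`, `predict()`, `evaluate_proxy()` (surrogates),
`latent_correlation()` (fixed-parameter convergent validity),
`run_ladder()` / `predict_trajectories()` (validation), and
`gain_importance()` / `shap_attributions()` / `beeswarm_export()`
(attribution). See the vignette for the models and all tuning constants.

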