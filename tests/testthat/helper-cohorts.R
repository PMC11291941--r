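# Shared fixtures, built in code once per test run.

small_building <- function() {
  simulate_model_building_cohort(generative_config(n_participants = 500L,
                                                   seed = 42L))
}

# A quick tuner: 3-fold CV over a narrowed tree-count range; used wherever a
# test needs *a* tuned surrogate rather than the tuning protocol itself.
quick_tuner <- function(seed = 1L, max_iterations = 3L,
                        patience = max_iterations, n_folds = 3L) {
  space <- default_search_space()
  space$lower[space$name == "nrounds"] <- 50
  space$upper[space$name == "nrounds"] <- 150
  space$upper[space$name == "max_depth"] <- 5
  tuner_config(n_folds = n_folds, max_iterations = max_iterations,
               patience = patience, search_space = space, seed = seed)
}

# Direct boosted fit with fixed, sensible hyperparameters (no tuning).
# Attribution tests use modest ensembles: TreeSHAP and prediction both run in
# single precision, so additivity is only meaningful a little above that.
quick_proxy <- function(train, criterion, tier, seed = 1L, nrounds = 150,
                        max_depth = 3, eta = 0.1) {
  fit_final(train, criterion, tier,
            list(max_depth = max_depth, eta = eta, nrounds = nrounds,
                 subsample = 1, colsample_bytree = 1, min_child_weight = 1,
                 lambda = 1),
            seed = seed)
}

# Design matrix of the default criterion model, for least-squares oracles.
rri_design_matrix <- function(cohort) {
  cbind(1, as.matrix(cohort[c("gm_signature", "log_wmh", "sex", "black_aa",
                              "hispanic", "prior_exposure", "spanish")]),
        cohort$prior_exposure * cohort$spanish)
}
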