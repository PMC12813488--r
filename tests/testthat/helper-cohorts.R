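# Small shared fixtures, built in code. The compact acquisition (one or two
# 120-volume runs at TR = 2.4 s) keeps runs eligible under the 4-minute rule
# while staying fast; the full-scale acquisition is exercised in the
# acceptance tests.

tiny_cfg <- function(n, n_parcels = 12, n_sites = 3, seed = 11, ...) {
  sim_config(n_subjects = n, n_parcels = n_parcels, n_sites = n_sites,
             n_runs = 1, volumes_per_run = 120, tr_seconds = 2.4,
             seed = seed, ...)
}

indicator_cols <- c("parent_duration", "child_duration", "device_duration")

# one cached small training cohort reused across test files
tiny_train <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      sim <- suppressMessages(simulate_cross_sectional(tiny_cfg(60, seed = 21)))
      ind <- sim$cohort[, indicator_cols]
      fm <- fit_factor(ind)
      cache <<- list(sim = sim, factor = fm,
                     y = factor_scores(fm, ind, "reduced"),
                     covars = standard_covariates(sim$cohort))
    }
    cache
  }
})

# exact sample-correlation data for a target 3x3 correlation matrix
exact_cor_data <- function(n, R, seed = 1) {
  set.seed(seed)
  MASS::mvrnorm(n, rep(0, nrow(R)), R, empirical = TRUE)
}
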