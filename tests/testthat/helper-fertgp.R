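# Shared fixtures, built in code. Expensive objects are cached per test run.

.fg_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.fg_cache[[key]])) assign(key, force(expr), envir = .fg_cache)
  .fg_cache[[key]]
}

# A constant-parameter truth (no SES/year dependence) with a broad curve.
flat_truth <- function(alpha = 10, beta = 2.7, rows_per_year = 2000,
                       years = 2005) {
  ground_truth(
    alpha_fn = function(ses, year) rep_len(alpha, length(ses)),
    beta_fn = function(ses, year) rep_len(beta, length(ses)),
    years = years, cohort_sizes = rows_per_year
  )
}

# Small, fast configuration for pipeline tests.
small_config <- function(seed = 1L, ...) {
  defaults <- list(age_quantiles = 40, ses_quantiles = 6, folds = 3,
                   gp_restarts = 4, gamma_restarts = 3, min_slice_trials = 30,
                   seed = seed)
  args <- utils::modifyList(defaults, list(...))
  do.call(fit_config, args)
}

# Default-scale synthetic dataset and fit, shared across test files.
default_fit <- function(seed) {
  cached(paste0("default_fit_", seed), {
    truth <- make_default_truth(rows_per_year = round(1e5 / 6))
    obs <- simulate_population(truth, seed = seed)
    model <- suppressWarnings(fit_fertility_model(obs, fit_config(seed = seed)))
    list(truth = truth, obs = obs, model = model)
  })
}

# Evaluation grid spanning the covariate hull, with ages at the central 90%
# of the truth's fertility age distribution (relative error in the far tails
# of the narrow rate curve is not a meaningful demographic quantity).
hull_grid <- function(truth) {
  a_mid <- truth$alpha_fn(2.5, 2006)
  b_mid <- truth$beta_fn(2.5, 2006)
  ages <- stats::qgamma(c(0.05, 0.25, 0.5, 0.75, 0.95), shape = a_mid) * b_mid
  expand.grid(age = ages, ses = c(1.5, 2.5, 3.5), year = truth$years)
}
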