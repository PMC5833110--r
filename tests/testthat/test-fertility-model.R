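# The combined pipeline: determinism, flat-truth behaviour, prediction
# identities and stratified refits. Small data and coarse bins keep these
# fast; end-to-end recovery at study scale lives in the acceptance tests.

make_obs <- function(rows = 4000, seed = 17, years = c(2001, 2005, 2009),
                     alpha_fn = NULL, beta_fn = NULL) {
  truth <- ground_truth(
    alpha_fn = alpha_fn %||% function(ses, year) rep_len(10, length(ses)),
    beta_fn = beta_fn %||% function(ses, year) rep_len(2.7, length(ses)),
    years = years, cohort_sizes = rows
  )
  list(truth = truth, obs = simulate_population(truth, seed = seed))
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("refitting with identical config and seed is bit-identical", {
  d <- make_obs(rows = 3000)
  cfg <- small_config(seed = 4)
  m1 <- suppressWarnings(fit_fertility_model(d$obs, cfg))
  m2 <- suppressWarnings(fit_fertility_model(d$obs, cfg))
  g <- expand.grid(age = seq(12, 50, by = 2), ses = c(1.5, 3), year = 2005)
  expect_identical(predict_fertility(m1, g$age, g$ses, g$year),
                   predict_fertility(m2, g$age, g$ses, g$year))
})

test_that("constant truth yields an essentially flat parameter surface", {
  d <- make_obs(rows = 8000, seed = 23)
  m <- suppressWarnings(fit_fertility_model(d$obs, small_config(seed = 23)))
  g <- expand.grid(ses = seq(1.2, 3.8, by = 0.2), year = c(2001, 2005, 2009))
  ab <- predict(m, data.frame(age = 25, ses = g$ses, year = g$year),
                what = "parameters")
  expect_lt(diff(range(ab$alpha)) / mean(ab$alpha), 0.05)
  expect_lt(diff(range(ab$beta)) / mean(ab$beta), 0.05)
  expect_true(all(ab$alpha > 0 & ab$beta > 0))
})

test_that("predictions are valid probabilities and smooth in SES", {
  d <- make_obs(rows = 4000)
  m <- suppressWarnings(fit_fertility_model(d$obs, small_config()))
  ses_grid <- seq(1, 4, by = 0.01)
  r <- predict_fertility(m, 24.3, ses_grid, 2005)
  expect_true(all(r >= 0 & r <= 1))
  # squared-exponential smoothing: no jumps on a fine SES grid
  expect_lt(max(abs(diff(r))), 0.01)
})

test_that("the predicted curve peaks at the smoothed (alpha - 1) * beta mode", {
  d <- make_obs(rows = 6000, seed = 29)
  m <- suppressWarnings(fit_fertility_model(d$obs, small_config(seed = 29)))
  pk <- peak_fertility(m, 2.5, 2005, age_grid = seq(10, 55, by = 0.01))
  ab <- predict(m, data.frame(age = 25, ses = 2.5, year = 2005),
                what = "parameters")
  expect_equal(pk$peak_age, (ab$alpha - 1) * ab$beta, tolerance = 1e-2)
})

test_that("degenerate inputs fail loudly", {
  d <- make_obs(rows = 40, seed = 2, years = 2005)
  expect_error(suppressWarnings(fit_fertility_model(d$obs, small_config())),
               "slice")
  obs_bad <- d$obs
  obs_bad$age[1] <- NA
  expect_error(fit_fertility_model(obs_bad, small_config()), "missing")
})

test_that("stratified fits conserve rows and agree for identical strata truths", {
  d <- make_obs(rows = 6000, seed = 41)
  sf <- suppressWarnings(stratified_fit(d$obs, "refugee", small_config(seed = 41)))
  expect_equal(sum(sf$counts), nrow(d$obs))
  # both strata were generated from the same truth: predictions agree in the
  # data-dense age band within Monte-Carlo error
  g <- expand.grid(age = seq(18, 35, by = 1), ses = 2.5, year = 2005)
  p0 <- predict_fertility(sf$models[["0"]], g$age, g$ses, g$year)
  p1 <- predict_fertility(sf$models[["1"]], g$age, g$ses, g$year)
  expect_lt(mean(abs(p0 - p1)) / mean(p0), 0.25)
  expect_error(stratified_fit(d$obs, "nonexistent", small_config()), "column")
})

test_that("strata with shifted peak ages are ordered correctly after refit", {
  late <- ground_truth(
    alpha_fn = function(ses, year) rep_len(16, length(ses)),
    beta_fn = function(ses, year) rep_len(2.2, length(ses)),
    years = c(2001, 2005, 2009), cohort_sizes = 1
  )
  truth <- ground_truth(
    alpha_fn = function(ses, year) rep_len(10, length(ses)),   # mode 24.3
    beta_fn = function(ses, year) rep_len(2.7, length(ses)),
    years = c(2001, 2005, 2009), cohort_sizes = 9000,
    refugee_truth = late, refugee_fraction = 0.5               # mode 33
  )
  obs <- simulate_population(truth, seed = 55)
  sf <- suppressWarnings(stratified_fit(obs, "refugee", small_config(seed = 55)))
  pk0 <- peak_fertility(sf$models[["0"]], 2.5, 2005)
  pk1 <- peak_fertility(sf$models[["1"]], 2.5, 2005)
  expect_gt(pk1$peak_age, pk0$peak_age)
})
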