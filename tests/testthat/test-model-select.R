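# Brier score, cross-validation, KS goodness of fit and the Bonferroni
# selection rule.

test_that("Brier score arithmetic is exact", {
  expect_equal(brier_score(c(1, 0, 1), c(1, 0, 1)), 0)
  expect_equal(brier_score(rep(0.5, 10), rbinom(10, 1, 0.5)), 0.25)
  expect_equal(brier_score(c(0.8, 0.3), c(1, 0)), (0.04 + 0.09) / 2)
  expect_error(brier_score(c(0.5, 0.5), 1), "length")
  # bounds: always within [0, 1], zero only at perfection
  set.seed(1)
  p <- runif(50); y <- rbinom(50, 1, p)
  expect_true(brier_score(p, y) >= 0 && brier_score(p, y) <= 1)
})

test_that("an oracle predictor beats a constant-rate predictor", {
  truth <- flat_truth(rows_per_year = 20000, years = 2005)
  obs <- simulate_population(truth, seed = 19)
  p_true <- true_rate(truth, obs$age, obs$ses, obs$year)
  expect_lt(brier_score(p_true, obs$y),
            brier_score(rep(mean(obs$y), nrow(obs)), obs$y))
})

test_that("cross-validation partitions cleanly and is seed-deterministic", {
  truth <- flat_truth(rows_per_year = 3000, years = c(2001, 2005, 2009))
  obs <- simulate_population(truth, seed = 31)
  cfg <- small_config(seed = 31)
  cv1 <- suppressWarnings(cross_validate(obs, cfg, folds = 3, seed = 31))
  cv2 <- suppressWarnings(cross_validate(obs, cfg, folds = 3, seed = 31))
  expect_identical(cv1$fold_scores, cv2$fold_scores)
  expect_equal(sum(cv1$fold_sizes), nrow(obs))
  expect_length(cv1$fold_scores, 3)
  expect_true(all(is.finite(cv1$fold_scores)))
  # pooled mean weights folds by their size
  expect_equal(cv1$mean,
               sum(cv1$fold_scores * cv1$fold_sizes) / nrow(obs))
  # grouping by woman keeps a woman's rows in one fold
  cfgw <- small_config(seed = 31, cv_group_by_woman = TRUE)
  cvw <- suppressWarnings(cross_validate(obs, cfgw, folds = 3, seed = 31))
  expect_true(all(is.finite(cvw$fold_scores)))
})

test_that("KS marginal comparison separates good and bad models", {
  expect_equal(fertgp:::ks_asymptotic_pvalue(0, 500), 1)
  expect_lt(fertgp:::ks_asymptotic_pvalue(0.5, 500), 1e-10)

  truth <- flat_truth(rows_per_year = 8000, years = c(2001, 2005, 2009))
  obs <- simulate_population(truth, seed = 47)
  m <- suppressWarnings(fit_fertility_model(obs, small_config(seed = 47)))
  good <- ks_age_marginal(m, obs)
  expect_gt(good$p_value, 0.001)

  # grossly shifted population: births peak ~9 years later than the model
  late <- flat_truth(alpha = 16, beta = 2.2, rows_per_year = 8000,
                     years = c(2001, 2005, 2009))
  obs_late <- simulate_population(late, seed = 48)
  bad <- ks_age_marginal(m, obs_late)
  expect_lt(bad$p_value, 1e-6)
  expect_gt(bad$statistic, good$statistic)

  no_births <- obs[obs$y == 0, ][1:100, ]
  expect_error(ks_age_marginal(m, no_births), "births")
})

test_that("selection applies the exact Bonferroni threshold and min-Brier rule", {
  truth <- flat_truth(rows_per_year = 2500, years = c(2001, 2005, 2009))
  obs <- simulate_population(truth, seed = 61)
  cands <- list(small_config(seed = 1),
                small_config(seed = 1, age_quantiles = 20, ses_quantiles = 4))
  rep2 <- suppressWarnings(select_model(obs, cands, level = 0.05, seed = 61))
  expect_equal(rep2$threshold, 0.05 / 2)
  expect_false(is.na(rep2$chosen))
  ok <- which(!rep2$table$rejected)
  expect_equal(rep2$table$mean_brier[rep2$chosen],
               min(rep2$table$mean_brier[ok]))
  # single candidate with acceptable fit is chosen
  rep1 <- suppressWarnings(select_model(obs, cands[1], level = 0.05, seed = 3))
  expect_equal(rep1$chosen, 1L)
})

test_that("a population the model family cannot express rejects all candidates", {
  # bimodal birth-age pattern: a single Gamma marginal cannot match it
  set.seed(71)
  n <- 30000
  age <- runif(n, 10, 55)
  rate <- 0.6 * pmin(dgamma(age, shape = 64, scale = 0.25), 1) +   # peak ~16
    0.6 * pmin(dgamma(age, shape = 110, scale = 0.4), 1)           # peak ~44
  obs <- data.frame(woman_id = sprintf("W-%06d", 1:n), year = 2005L,
                    age = age, ses = runif(n, 1, 4), refugee = 0L,
                    education = 5L, y = rbinom(n, 1, rate))
  rep <- suppressWarnings(select_model(obs, list(small_config(seed = 5)),
                                       level = 0.05, seed = 5))
  expect_true(all(rep$table$rejected))
  expect_identical(rep$status, "all candidates rejected")
  expect_true(is.na(rep$chosen))
})
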