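# Model selection: ten-fold cross-validated Brier score, a Kolmogorov-
# Smirnov comparison of the model-implied and empirical birth-age
# distributions, and Bonferroni-corrected rejection across the candidate
# set.

#' Brier score for probabilistic binary predictions
#'
#' `mean((outcomes - predicted)^2)`: zero iff predictions equal outcomes
#' exactly, 0.25 for a constant 0.5 predictor.
#'
#' @param predicted probabilities in `[0, 1]`.
#' @param outcomes binary outcomes, same length.
#' @return scalar in `[0, 1]`.
#' @export
brier_score <- function(predicted, outcomes) {
  if (length(predicted) != length(outcomes)) {
    stop("predicted and outcomes must have equal length")
  }
  stopifnot(all(predicted >= 0), all(predicted <= 1),
            all(outcomes %in% c(0, 1)))
  mean((outcomes - predicted)^2)
}

#' Cross-validated Brier score of the combined model
#'
#' Partitions woman-years uniformly at random into folds (seeded; optionally
#' grouped by woman via `config$cv_group_by_woman`), refits the full
#' pipeline on each training complement, and scores held-out rows at their
#' unbinned `(age, ses, year)` values. The pooled mean weights folds by
#' size, i.e. it is the mean over all held-out observations.
#'
#' @param obs observation table.
#' @param config a [fit_config()].
#' @param folds number of folds.
#' @param seed seed for the fold partition.
#' @return object of class `cv_result`: `mean`, `fold_scores`,
#'   `fold_sizes`, `failed` (indices of folds whose training fit failed;
#'   any failure makes `mean` `NA` so the candidate is flagged, not
#'   silently skipped).
#' @export
cross_validate <- function(obs, config = fit_config(), folds = config$folds,
                           seed = config$seed) {
  validate_obs_table(obs)
  stopifnot(folds >= 2)
  n <- nrow(obs)
  assign <- with_seed(seed, {
    if (isTRUE(config$cv_group_by_woman)) {
      women <- unique(obs$woman_id)
      wf <- sample(rep_len(seq_len(folds), length(women)))
      wf[match(obs$woman_id, women)]
    } else {
      sample(rep_len(seq_len(folds), n))
    }
  })
  fold_scores <- rep(NA_real_, folds)
  fold_sizes <- tabulate(assign, folds)
  failed <- integer(0)
  for (k in seq_len(folds)) {
    test <- obs[assign == k, , drop = FALSE]
    train <- obs[assign != k, , drop = FALSE]
    fit <- tryCatch(fit_fertility_model(train, config),
                    error = function(e) e)
    if (inherits(fit, "error")) {
      failed <- c(failed, k)
      next
    }
    p <- predict_fertility(fit, test$age, test$ses, test$year)
    fold_scores[k] <- brier_score(p, test$y)
  }
  mean_score <- if (length(failed)) NA_real_ else {
    sum(fold_scores * fold_sizes) / sum(fold_sizes)
  }
  structure(list(mean = mean_score, fold_scores = fold_scores,
                 fold_sizes = fold_sizes, failed = failed, seed = seed),
            class = "cv_result")
}

# Asymptotic one-sample Kolmogorov p-value for statistic D at sample size n
# (Stephens' small-sample adjustment of the Kolmogorov series).
ks_asymptotic_pvalue <- function(D, n) {
  lambda <- (sqrt(n) + 0.12 + 0.11 / sqrt(n)) * D
  if (lambda < 1e-3) return(1)
  k <- seq_len(101)
  p <- 2 * sum((-1)^(k - 1) * exp(-2 * k^2 * lambda^2))
  min(max(p, 0), 1)
}

#' KS goodness of fit of the model's marginal age distribution of births
#'
#' The empirical distribution is the set of ages of woman-years with a live
#' birth. The model distribution is formed by summing the predicted rates
#' `predict(a, x_i)` over all observed covariate rows for each age on a
#' grid, then normalising to a distribution over age. The statistic is the
#' sup distance between the two CDFs evaluated on the grid; the p-value is
#' the asymptotic one-sample Kolmogorov formula with `n` equal to the
#' number of births.
#'
#' Comparing two fitted rate curves is not a textbook KS setting; this
#' normalised-marginal construction is the interpretation adopted
#' throughout the package (see the methods vignette).
#'
#' @param model a `fertility_model`.
#' @param obs observation table containing at least one birth.
#' @param grid_points number of age-grid points.
#' @return list with `statistic`, `p_value`, `n_births`.
#' @export
ks_age_marginal <- function(model, obs, grid_points = 256) {
  validate_obs_table(obs)
  birth_ages <- obs$age[obs$y == 1]
  n_b <- length(birth_ages)
  if (n_b == 0) stop("observation table contains no births")
  ab <- predict_ab(model, obs$ses, obs$year)
  grid <- seq(min(obs$age), max(obs$age), length.out = grid_points)
  M <- vapply(grid, function(a) {
    sum(pmin(stats::dgamma(a, shape = ab$alpha, scale = ab$beta), 1))
  }, numeric(1))
  if (sum(M) <= 0) stop("model-implied marginal is identically zero")
  F_model <- cumsum(M) / sum(M)
  F_emp <- stats::ecdf(birth_ages)(grid)
  D <- max(abs(F_model - F_emp))
  list(statistic = D, p_value = ks_asymptotic_pvalue(D, n_b), n_births = n_b)
}

#' Choose quantile counts / model variants by CV Brier and KS rejection
#'
#' Evaluates every candidate configuration's cross-validated Brier score and
#' KS p-value, rejects candidates with `p < level / n_candidates`
#' (Bonferroni across the tests performed), and chooses the minimum mean
#' Brier among non-rejected candidates. Candidates whose fits fail are
#' flagged and treated as rejected.
#'
#' @param obs observation table.
#' @param candidates list of [fit_config()] objects.
#' @param level familywise significance level.
#' @param seed master seed; each candidate gets a derived seed.
#' @return object of class `model_selection_report`: a per-candidate table,
#'   the Bonferroni threshold, the chosen candidate index (or `NA` with
#'   `status = "all candidates rejected"`), and the full CV/KS details.
#' @export
select_model <- function(obs, candidates, level = 0.05, seed = 1L) {
  stopifnot(length(candidates) >= 1)
  m <- length(candidates)
  threshold <- level / m
  rows <- vector("list", m)
  details <- vector("list", m)
  for (j in seq_len(m)) {
    cfg <- candidates[[j]]
    stopifnot(inherits(cfg, "fit_config"))
    cv <- cross_validate(obs, cfg, seed = derive_seed(seed, j))
    fit <- tryCatch(fit_fertility_model(obs, cfg), error = function(e) e)
    if (inherits(fit, "error")) {
      ks <- list(statistic = NA_real_, p_value = NA_real_, n_births = NA_integer_)
      fit_failed <- TRUE
    } else {
      ks <- ks_age_marginal(fit, obs)
      fit_failed <- FALSE
    }
    rejected <- fit_failed || length(cv$failed) > 0 ||
      (is.finite(ks$p_value) && ks$p_value < threshold)
    rows[[j]] <- data.frame(
      candidate = j,
      age_quantiles = cfg$age_quantiles,
      ses_quantiles = cfg$ses_quantiles,
      mean_brier = cv$mean,
      ks_statistic = ks$statistic,
      ks_p = ks$p_value,
      rejected = rejected
    )
    details[[j]] <- list(config = cfg, cv = cv, ks = ks, fit_failed = fit_failed)
  }
  tab <- do.call(rbind, rows)
  eligible <- which(!tab$rejected & is.finite(tab$mean_brier))
  chosen <- if (length(eligible)) eligible[which.min(tab$mean_brier[eligible])] else NA_integer_
  structure(list(table = tab, threshold = threshold, level = level,
                 chosen = chosen,
                 status = if (is.na(chosen)) "all candidates rejected" else "ok",
                 details = details, seed = seed),
            class = "model_selection_report")
}

#' @export
print.model_selection_report <- function(x, ...) {
  cat(sprintf("Model selection over %d candidates (Bonferroni threshold %.6g)\n",
              nrow(x$table), x$threshold))
  print(x$table, row.names = FALSE)
  if (is.na(x$chosen)) {
    cat("status:", x$status, "\n")
  } else {
    cat(sprintf("chosen: candidate %d (mean Brier %.6g)\n",
                x$chosen, x$table$mean_brier[x$chosen]))
  }
  invisible(x)
}
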