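# The combined model: quantile-bin the observations, fit a Gamma age-pattern
# per (SES-bin x year) slice by maximum likelihood, then smooth log(alpha)
# and log(beta) over (SES, year) with two independent Gaussian processes.
# Prediction composes the GP means with the Gamma rate curve.

#' Configuration for the combined fertility fit
#'
#' @param age_quantiles,ses_quantiles quantile-bin counts; the defaults
#'   suit census-scale tables and should be re-selected per dataset with
#'   [select_model()].
#' @param level significance level for goodness-of-fit rejection.
#' @param folds cross-validation folds.
#' @param bootstrap_reps parametric bootstrap replicates.
#' @param ses_prior `c(shape, scale)` of the Gamma smoothing prior on the
#'   SES lengthscale (default `c(6, 0.25)`, mode `(6-1)*0.25 = 1.25`), or
#'   `NULL` for no prior.
#' @param seed seed driving every stochastic step of the fit.
#' @param min_slice_trials slices with fewer total trials are excluded from
#'   GP training.
#' @param gamma_restarts,gp_restarts optimiser restart counts.
#' @param bootstrap_gp_restarts restarts used for GP refits inside the
#'   parametric bootstrap (warm-started at the original fit).
#' @param slice_bias_correct how to handle the small-sample bias of the
#'   per-slice Gamma shape/scale MLEs before GP smoothing: `"calibrate"`
#'   (default) estimates the ensemble log-scale bias by refitting simulated
#'   replicate slices at the fitted parameters and iterating to a fixed
#'   point; `"analytic"` uses the first-order `alpha * k/(k+3)` correction
#'   of [fit_gamma_slice()]; `"none"` smooths the raw MLEs.
#' @param calibration_replicates,calibration_iterations simulated replicate
#'   slices per fitted slice and fixed-point iterations used by the
#'   `"calibrate"` bias correction.
#' @param gp_parameterisation coordinates smoothed by the two GPs.
#'   `"mean-shape"` (default) smooths `log(alpha * beta)` (the log mean age
#'   of the curve) and `log(alpha)`: the slice MLEs of shape and scale are
#'   strongly negatively correlated (the mean age of births is estimated
#'   precisely, the curve width poorly), and these near-orthogonal
#'   coordinates give each GP a noise level commensurate with its signal.
#'   `"shape-scale"` smooths `log(alpha)` and `log(beta)` directly. Both
#'   guarantee positive predicted parameters.
#' @param per_year_gp fit separate per-year GPs over SES instead of one GP
#'   over (SES, year).
#' @param pooled_quantiles compute bin edges pooled across years (default)
#'   or per year.
#' @param cv_group_by_woman partition cross-validation folds by woman rather
#'   than by woman-year.
#' @return object of class `fit_config`.
#' @export
fit_config <- function(age_quantiles = 125, ses_quantiles = 25,
                       level = 0.05, folds = 10, bootstrap_reps = 1000,
                       ses_prior = c(shape = 6, scale = 0.25),
                       seed = 1L, min_slice_trials = 50,
                       gamma_restarts = 5, gp_restarts = 10,
                       bootstrap_gp_restarts = 2,
                       slice_bias_correct = c("calibrate", "analytic", "none"),
                       calibration_replicates = 2, calibration_iterations = 2,
                       gp_parameterisation = c("mean-shape", "shape-scale"),
                       per_year_gp = FALSE, pooled_quantiles = TRUE,
                       cv_group_by_woman = FALSE) {
  stopifnot(age_quantiles >= 1, ses_quantiles >= 1, folds >= 2,
            level > 0, level < 1, bootstrap_reps >= 1, min_slice_trials >= 0)
  slice_bias_correct <- match.arg(slice_bias_correct)
  gp_parameterisation <- match.arg(gp_parameterisation)
  structure(list(age_quantiles = age_quantiles, ses_quantiles = ses_quantiles,
                 level = level, folds = folds, bootstrap_reps = bootstrap_reps,
                 ses_prior = ses_prior, seed = as.integer(seed),
                 min_slice_trials = min_slice_trials,
                 gamma_restarts = gamma_restarts, gp_restarts = gp_restarts,
                 bootstrap_gp_restarts = bootstrap_gp_restarts,
                 slice_bias_correct = slice_bias_correct,
                 calibration_replicates = calibration_replicates,
                 calibration_iterations = calibration_iterations,
                 gp_parameterisation = gp_parameterisation,
                 per_year_gp = per_year_gp,
                 pooled_quantiles = pooled_quantiles,
                 cv_group_by_woman = cv_group_by_woman),
            class = "fit_config")
}

#' Fit the combined Gamma-age / GP-covariate fertility model
#'
#' Pipeline: bin ages and SES into quantiles ([bin_spec()]), compute
#' empirical rates per (age-bin x SES-bin x year) cell, fit one Gamma
#' age-pattern per (SES-bin x year) slice ([fit_gamma_slice()]), then fit
#' two GPs ([fit_gp()]) to `log(alpha_hat)` and `log(beta_hat)` at the slice
#' midpoints over the covariate vector `(ses, year)`, with the smoothing
#' prior on the SES lengthscale. Fitting on the log scale guarantees
#' strictly positive predicted parameters. Deterministic given
#' `config$seed`.
#'
#' @param obs observation table (see [validate_obs_table()]).
#' @param config a [fit_config()].
#' @param warm_start optional list with `h1`/`h2` `kernel_hyperparams` used
#'   as additional GP optimiser starts.
#' @return object of class `fertility_model`.
#' @export
fit_fertility_model <- function(obs, config = fit_config(), warm_start = NULL) {
  validate_obs_table(obs)
  stopifnot(inherits(config, "fit_config"))
  spec <- bin_spec(obs, age_q = config$age_quantiles,
                   ses_q = config$ses_quantiles,
                   per_year = !config$pooled_quantiles)
  binned <- empirical_rates(obs, spec)

  key <- interaction(binned$ses_mid, binned$year, drop = TRUE)
  slices <- split(binned, key)
  fits <- vector("list", length(slices))
  meta <- data.frame(ses_mid = numeric(length(slices)),
                     year = integer(length(slices)),
                     alpha = NA_real_, beta = NA_real_,
                     n_eff = 0L, used = FALSE)
  for (k in seq_along(slices)) {
    cells <- slices[[k]]
    sid <- sprintf("ses=%.4g|year=%d", cells$ses_mid[1], cells$year[1])
    fits[[k]] <- fit_gamma_slice(cells, slice_id = sid,
                                 n_restarts = config$gamma_restarts,
                                 seed = derive_seed(config$seed, k))
    meta$ses_mid[k] <- cells$ses_mid[1]
    meta$year[k] <- cells$year[1]
    if (identical(config$slice_bias_correct, "analytic")) {
      meta$alpha[k] <- fits[[k]]$alpha_bc
      meta$beta[k] <- fits[[k]]$beta_bc
    } else {
      meta$alpha[k] <- fits[[k]]$alpha
      meta$beta[k] <- fits[[k]]$beta
    }
    meta$n_eff[k] <- fits[[k]]$n_eff
  }
  # A slice is usable when it converged, is populated, its log-parameters
  # are finite (guards against under/overflow on near-empty slices), and its
  # fitted mode lies within (a margin of) the observed age support -- a fit
  # whose peak sits outside the data is an artefact of a handful of births.
  age_support <- range(binned$age_mid)
  slice_mode <- (meta$alpha - 1) * meta$beta
  meta$used <- vapply(fits, function(f) isTRUE(f$converged), logical(1)) &
    meta$n_eff >= config$min_slice_trials &
    is.finite(log(pmax(meta$alpha, 0))) & is.finite(log(pmax(meta$beta, 0))) &
    is.finite(slice_mode) &
    slice_mode > age_support[1] - 10 & slice_mode < age_support[2] + 10
  n_dropped <- sum(!meta$used)
  if (n_dropped > 0) {
    warning(sprintf("%d of %d covariate slices unusable (sparse or unconverged); excluded from GP training",
                    n_dropped, nrow(meta)))
  }
  if (sum(meta$used) < 3) {
    stop("fewer than 3 usable covariate slices; cannot smooth parameters")
  }
  fg_log(sprintf("fitted %d slices (%d usable) from %d cells",
                 nrow(meta), sum(meta$used), nrow(binned)))

  bias_calibration <- NULL
  if (identical(config$slice_bias_correct, "calibrate")) {
    bias_calibration <- calibrate_slice_bias(
      slices[meta$used], log(meta$alpha[meta$used]), log(meta$beta[meta$used]),
      seed = derive_seed(config$seed, 999),
      replicates = config$calibration_replicates,
      iterations = config$calibration_iterations)
    meta$alpha[meta$used] <- exp(log(meta$alpha[meta$used]) - bias_calibration$bias_log_alpha)
    meta$beta[meta$used] <- exp(log(meta$beta[meta$used]) - bias_calibration$bias_log_beta)
  }

  used <- meta[meta$used, ]
  prior <- if (is.null(config$ses_prior)) NULL else list(config$ses_prior, NULL)

  # GP smoothing targets in the configured coordinates.
  if (config$gp_parameterisation == "mean-shape") {
    t1 <- log(used$alpha * used$beta)   # log mean age of the curve
    t2 <- log(used$alpha)               # log shape (curve width)
  } else {
    t1 <- log(used$alpha)
    t2 <- log(used$beta)
  }

  if (config$per_year_gp) {
    yrs <- sort(unique(used$year))
    fit_year_gps <- function(targets, offset) {
      out <- lapply(yrs, function(yr) {
        i <- used$year == yr
        if (sum(i) < 3) stop("fewer than 3 usable slices in year ", yr)
        fit_gp(gp_training_set(matrix(used$ses_mid[i], ncol = 1), targets[i]),
               prior = if (is.null(prior)) NULL else prior[1],
               seed = derive_seed(config$seed, offset + yr),
               n_restarts = config$gp_restarts)
      })
      names(out) <- as.character(yrs)
      out
    }
    gp1 <- fit_year_gps(t1, 100)
    gp2 <- fit_year_gps(t2, 200)
  } else {
    X <- cbind(ses = used$ses_mid, year = as.numeric(used$year))
    gp1 <- fit_gp(gp_training_set(X, t1), prior = prior,
                  seed = derive_seed(config$seed, 101),
                  n_restarts = config$gp_restarts,
                  h0 = warm_start$h1)
    gp2 <- fit_gp(gp_training_set(X, t2), prior = prior,
                  seed = derive_seed(config$seed, 102),
                  n_restarts = config$gp_restarts,
                  h0 = warm_start$h2)
  }

  structure(list(gp1 = gp1, gp2 = gp2, bin_spec = spec,
                 slice_fits = fits, slice_table = meta,
                 bias_calibration = bias_calibration, config = config,
                 n_obs = nrow(obs),
                 ses_hull = range(used$ses_mid),
                 years = sort(unique(used$year))),
            class = "fertility_model")
}

# Ensemble calibration of the per-slice MLE bias. The Gamma shape MLE from a
# slice holding few births is biased (upward in the shape, downward in the
# scale, on the log scale by roughly 3/births). The bias is estimated by
# simulation from the fitted slices themselves: replicate birth counts are
# drawn at each slice's own cell layout, refitted, and the mean log-scale
# displacement measured; iterating the correction solves the fixed point
# theta_hat = theta + bias(theta). The estimate is an ensemble average, so
# its Monte-Carlo error shrinks with the slice count.
calibrate_slice_bias <- function(cell_list, log_alpha, log_beta, seed,
                                 replicates = 2, iterations = 2) {
  c_a <- 0; c_b <- 0
  for (it in seq_len(iterations)) {
    d_a <- numeric(0); d_b <- numeric(0)
    for (i in seq_along(cell_list)) {
      cells <- cell_list[[i]]
      al <- exp(log_alpha[i] - c_a); be <- exp(log_beta[i] - c_b)
      p <- clamp01(stats::dgamma(cells$age_mid, shape = al, scale = be))
      for (r in seq_len(replicates)) {
        sb <- derive_seed(seed, it * 100000 + i * 10 + r)
        births <- with_seed(sb, stats::rbinom(nrow(cells), cells$n_trials, p))
        rep_cells <- data.frame(age_mid = cells$age_mid,
                                n_trials = cells$n_trials, n_births = births)
        f <- fit_gamma_slice(rep_cells, n_restarts = 1, seed = sb)
        la <- suppressWarnings(log(f$alpha)); lb <- suppressWarnings(log(f$beta))
        # degenerate replicate refits (handfuls of births) are excluded, as
        # are fits whose mode escaped the age support of the cells
        f_mode <- (f$alpha - 1) * f$beta
        if (isTRUE(f$converged) && is.finite(la) && is.finite(lb) &&
            is.finite(f_mode) &&
            f_mode > min(cells$age_mid) - 10 && f_mode < max(cells$age_mid) + 10) {
          d_a <- c(d_a, la - (log_alpha[i] - c_a))
          d_b <- c(d_b, lb - (log_beta[i] - c_b))
        }
      }
    }
    if (length(d_a) == 0) break
    c_a <- mean(d_a)
    c_b <- mean(d_b)
  }
  list(bias_log_alpha = c_a, bias_log_beta = c_b,
       n_replicates = length(d_a))
}

# GP-smoothed (alpha, beta) at arbitrary covariate points, converting back
# from the configured GP coordinates.
predict_ab <- function(model, ses, year) {
  n <- max(length(ses), length(year))
  ses <- rep_len(ses, n); year <- rep_len(year, n)
  if (model$config$per_year_gp) {
    v1 <- numeric(n); v2 <- numeric(n)
    for (yr in unique(year)) {
      i <- year == yr
      g1 <- model$gp1[[as.character(yr)]]
      g2 <- model$gp2[[as.character(yr)]]
      if (is.null(g1)) stop("no per-year GP for year ", yr)
      v1[i] <- predict(g1, matrix(ses[i], ncol = 1))
      v2[i] <- predict(g2, matrix(ses[i], ncol = 1))
    }
  } else {
    Xq <- cbind(ses = ses, year = as.numeric(year))
    v1 <- predict(model$gp1, Xq)
    v2 <- predict(model$gp2, Xq)
  }
  gp_coords_to_ab(model$config$gp_parameterisation, v1, v2)
}

gp_coords_to_ab <- function(parameterisation, v1, v2) {
  if (parameterisation == "mean-shape") {
    list(alpha = exp(v2), beta = exp(v1 - v2))  # beta = mean / shape
  } else {
    list(alpha = exp(v1), beta = exp(v2))
  }
}

#' Predicted fertility rate at given age and covariates
#'
#' Composes the GP posterior means for `log(alpha)` and `log(beta)` at
#' `(ses, year)` with the Gamma rate curve over age. Querying outside the
#' SES training hull is permitted (the GP extrapolates smoothly) but should
#' be interpreted with care.
#'
#' @param model a fitted `fertility_model`.
#' @param age,ses,year vectors, recycled to a common length.
#' @return fertility rates in `[0, 1]`.
#' @export
predict_fertility <- function(model, age, ses, year) {
  stopifnot(inherits(model, "fertility_model"))
  n <- max(length(age), length(ses), length(year))
  age <- rep_len(age, n)
  ab <- predict_ab(model, rep_len(ses, n), rep_len(year, n))
  gamma_fertility_rate(age, ab$alpha, ab$beta)
}

#' @param object a `fertility_model`.
#' @param newdata data.frame with columns `age`, `ses`, `year`.
#' @param what `"rate"` for fertility rates, `"parameters"` for the
#'   GP-smoothed `alpha`/`beta`.
#' @param ... unused.
#' @rdname predict_fertility
#' @export
predict.fertility_model <- function(object, newdata,
                                    what = c("rate", "parameters"), ...) {
  what <- match.arg(what)
  stopifnot(all(c("age", "ses", "year") %in% names(newdata)))
  if (what == "rate") {
    predict_fertility(object, newdata$age, newdata$ses, newdata$year)
  } else {
    ab <- predict_ab(object, newdata$ses, newdata$year)
    data.frame(alpha = ab$alpha, beta = ab$beta)
  }
}

#' Independent fits on two strata of the data
#'
#' Splits the observation table on a binary flag column (e.g. refugee
#' status) and runs the identical pipeline — same covariates and quantile
#' counts, bin edges recomputed within each stratum — on each part.
#'
#' @param obs observation table.
#' @param flag_column name of a binary column of `obs`.
#' @param config a [fit_config()] applied to both strata.
#' @return object of class `stratified_fertility_fit`: list of two
#'   `fertility_model`s named by flag value, plus stratum counts.
#' @export
stratified_fit <- function(obs, flag_column = "refugee", config = fit_config()) {
  validate_obs_table(obs)
  if (!flag_column %in% names(obs)) stop("no column named ", flag_column)
  flag <- obs[[flag_column]]
  if (anyNA(flag) || !all(flag %in% c(0, 1))) {
    stop(flag_column, " must be binary (0/1) with no missing values")
  }
  if (!any(flag == 0) || !any(flag == 1)) {
    stop("both strata of ", flag_column, " must be non-empty")
  }
  models <- lapply(c(0, 1), function(v) {
    fit_fertility_model(obs[flag == v, , drop = FALSE], config)
  })
  names(models) <- c("0", "1")
  structure(list(models = models, flag_column = flag_column,
                 counts = c("0" = sum(flag == 0), "1" = sum(flag == 1))),
            class = "stratified_fertility_fit")
}

#' Age at which the predicted fertility curve peaks
#'
#' Numeric argmax over a fine age grid; for the Gamma curve this equals
#' `(alpha - 1) * beta` up to grid resolution.
#'
#' @param model a `fertility_model`.
#' @param ses,year covariate point.
#' @param age_grid evaluation grid (default 0.02-year resolution over 10-55).
#' @return list with `peak_age` and `peak_rate`.
#' @export
peak_fertility <- function(model, ses, year,
                           age_grid = seq(10, 55, by = 0.02)) {
  r <- predict_fertility(model, age_grid, ses, year)
  i <- which.max(r)
  list(peak_age = age_grid[i], peak_rate = r[i])
}

#' @export
print.fertility_model <- function(x, ...) {
  cat("Combined Gamma-age / GP fertility model\n")
  cat(sprintf("  observations: %d woman-years; years %s\n", x$n_obs,
              paste(x$years, collapse = ", ")))
  cat(sprintf("  bins: %d age quantiles x %d SES quantiles\n",
              x$config$age_quantiles, x$config$ses_quantiles))
  cat(sprintf("  slices: %d fitted, %d used for GP smoothing\n",
              nrow(x$slice_table), sum(x$slice_table$used)))
  if (!x$config$per_year_gp) {
    nm <- if (x$config$gp_parameterisation == "mean-shape") {
      c("log-mean ", "log-shape")
    } else c("log-alpha", "log-beta ")
    cat(sprintf("  %s GP lengthscales (ses, year): %s\n", nm[1],
                paste(signif(x$gp1$h$lengthscales, 3), collapse = ", ")))
    cat(sprintf("  %s GP lengthscales (ses, year): %s\n", nm[2],
                paste(signif(x$gp2$h$lengthscales, 3), collapse = ", ")))
  }
  invisible(x)
}
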