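# Parametric bootstrap bands for fitted fertility curves: simulate birth
# indicators from the fitted rate surface at the observed covariates, refit
# the whole pipeline, evaluate the refitted curve on a grid, and take
# pointwise percentiles across replicates.

#' Parametric bootstrap confidence bands
#'
#' Default mode `"refit"`: each replicate draws `Y* ~ Bernoulli(p_hat)` at
#' the observed covariates, refits the full pipeline (slice Gamma fits and
#' GP hyperparameter re-optimisation, warm-started at the original fit with
#' `config$bootstrap_gp_restarts` restarts) and evaluates the refitted rate
#' curve on the grid. Mode `"gp-draw"` is a cheaper alternative that skips
#' refitting and instead draws `log(alpha)`/`log(beta)` surfaces from the
#' fitted GP posteriors at the grid covariates.
#'
#' Bands are pointwise percentiles (2.5, 25, 50, 75, 97.5) across
#' replicates. Replicates whose refit fails are dropped and counted; more
#' than 10% dropped is an error.
#'
#' @param model a fitted `fertility_model`.
#' @param obs the observation table the model layout matches.
#' @param grid data.frame with columns `age`, `ses`, `year` (the evaluation
#'   points, e.g. an age sweep at fixed SES and year).
#' @param B number of bootstrap replicates (default 1000).
#' @param seed seed; the run is reproducible.
#' @param mode `"refit"` (full parametric bootstrap) or `"gp-draw"`.
#' @return object of class `bootstrap_bands`: the grid, a `5 x nrow(grid)`
#'   matrix of band quantiles, replicate counts, and the seed.
#' @export
parametric_bootstrap <- function(model, obs, grid, B = 1000, seed = 1L,
                                 mode = c("refit", "gp-draw")) {
  mode <- match.arg(mode)
  stopifnot(inherits(model, "fertility_model"), B >= 1,
            all(c("age", "ses", "year") %in% names(grid)))
  validate_obs_table(obs)
  G <- nrow(grid)

  if (mode == "refit") {
    p_hat <- predict_fertility(model, obs$age, obs$ses, obs$year)
    cfg <- model$config
    cfg$gp_restarts <- cfg$bootstrap_gp_restarts
    warm <- if (cfg$per_year_gp) NULL else
      list(h1 = model$gp1$h, h2 = model$gp2$h)
    curves <- matrix(NA_real_, nrow = B, ncol = G)
    dropped <- 0L
    for (b in seq_len(B)) {
      sb <- derive_seed(seed, b)
      res <- tryCatch({
        obs_b <- obs
        obs_b$y <- with_seed(sb, stats::rbinom(nrow(obs), 1L, p_hat))
        cfg_b <- cfg
        cfg_b$seed <- sb
        fit_b <- suppressWarnings(fit_fertility_model(obs_b, cfg_b,
                                                      warm_start = warm))
        predict_fertility(fit_b, grid$age, grid$ses, grid$year)
      }, error = function(e) NULL)
      if (is.null(res)) dropped <- dropped + 1L else curves[b, ] <- res
    }
    if (dropped > 0.1 * B) {
      stop(sprintf("%d of %d bootstrap refits failed (more than 10%%)",
                   dropped, B))
    }
    curves <- curves[stats::complete.cases(curves), , drop = FALSE]
  } else {
    # Draw latent log-parameter surfaces from the GP posteriors at the
    # grid's covariate points (no refit; narrower bands, no slice-fit
    # uncertainty).
    if (model$config$per_year_gp) {
      stop("gp-draw mode requires the single (ses, year) GP layout")
    }
    Xq <- cbind(ses = grid$ses, year = as.numeric(grid$year))
    draw_surface <- function(gp, sub_seed) {
      post <- gp_posterior(Xq, gp$train, gp$h, include_noise = FALSE)
      U <- gp_chol(post$cov + diag(1e-10, G))$U
      Z <- with_seed(sub_seed, matrix(stats::rnorm(B * G), nrow = B))
      sweep(Z %*% U, 2, post$mean + gp$y_mean, "+")
    }
    v1 <- draw_surface(model$gp1, derive_seed(seed, 1))
    v2 <- draw_surface(model$gp2, derive_seed(seed, 2))
    curves <- matrix(NA_real_, nrow = B, ncol = G)
    for (b in seq_len(B)) {
      ab <- gp_coords_to_ab(model$config$gp_parameterisation, v1[b, ], v2[b, ])
      curves[b, ] <- gamma_fertility_rate(grid$age, ab$alpha, ab$beta)
    }
    dropped <- 0L
  }

  bands <- apply(curves, 2, stats::quantile,
                 probs = c(0.025, 0.25, 0.5, 0.75, 0.975), type = 7)
  rownames(bands) <- c("q2.5", "q25", "q50", "q75", "q97.5")
  structure(list(grid = grid, bands = bands, B = B,
                 B_used = nrow(curves), dropped = dropped,
                 seed = seed, mode = mode),
            class = "bootstrap_bands")
}

#' @export
print.bootstrap_bands <- function(x, ...) {
  cat(sprintf("Parametric bootstrap bands (%s mode): %d/%d replicates over %d grid points\n",
              x$mode, x$B_used, x$B, nrow(x$grid)))
  invisible(x)
}
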