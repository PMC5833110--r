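# Synthetic woman-year data generator with a known ground-truth fertility
# surface. Emulates the structure of repeated HDSS census rounds: one row per
# woman per census year, a continuous SES index, and a binary live-birth
# indicator whose success probability follows a Gamma-in-age curve that
# varies smoothly with SES and year.

#' Define a ground-truth fertility surface
#'
#' The truth object specifies how the Gamma age-pattern parameters vary over
#' covariates, the covariate ranges, the census years and the number of
#' woman-year rows per year. [simulate_population()] draws Bernoulli birth
#' indicators from the implied rate surface.
#'
#' @param alpha_fn function `(ses, year) -> shape`; must return strictly
#'   positive finite values over the stated ranges (vectorised).
#' @param beta_fn function `(ses, year) -> scale` in years; same requirements.
#' @param age_range closed interval of ages in years.
#' @param ses_range closed interval of the SES index.
#' @param years integer census years.
#' @param cohort_sizes number of woman-year rows per census year (recycled to
#'   `length(years)`).
#' @param age_sampler optional function `(n) -> ages`; defaults to uniform on
#'   `age_range`. The real population pyramid is not modelled.
#' @param ses_sampler optional function `(n) -> ses`; defaults to uniform on
#'   `ses_range`.
#' @param refugee_truth optional second `ground_truth` used for the refugee
#'   stratum; when `NULL` the refugee flag is an independent label with no
#'   rate difference.
#' @param refugee_fraction fraction of rows flagged as refugee.
#' @return object of class `ground_truth`.
#' @seealso [make_default_truth()], [simulate_population()]
#' @export
ground_truth <- function(alpha_fn, beta_fn,
                         age_range = c(10, 55),
                         ses_range = c(1, 4),
                         years = seq(2001, 2011, by = 2),
                         cohort_sizes = 37440L,
                         age_sampler = NULL,
                         ses_sampler = NULL,
                         refugee_truth = NULL,
                         refugee_fraction = 0.3) {
  stopifnot(is.function(alpha_fn), is.function(beta_fn),
            length(age_range) == 2, age_range[1] < age_range[2],
            length(ses_range) == 2, ses_range[1] < ses_range[2],
            length(years) >= 1, all(is.finite(years)),
            all(cohort_sizes >= 1),
            refugee_fraction >= 0, refugee_fraction <= 1)
  truth <- structure(list(
    alpha_fn = alpha_fn,
    beta_fn = beta_fn,
    age_range = as.numeric(age_range),
    ses_range = as.numeric(ses_range),
    years = as.integer(years),
    cohort_sizes = as.integer(rep_len(cohort_sizes, length(years))),
    age_sampler = age_sampler,
    ses_sampler = ses_sampler,
    refugee_truth = refugee_truth,
    refugee_fraction = refugee_fraction
  ), class = "ground_truth")
  validate_ground_truth(truth)
  truth
}

# Probe alpha/beta over a covariate grid; reject non-finite or non-positive
# values before any simulation is attempted.
validate_ground_truth <- function(truth) {
  stopifnot(inherits(truth, "ground_truth"))
  ses <- seq(truth$ses_range[1], truth$ses_range[2], length.out = 9)
  grid <- expand.grid(ses = ses, year = truth$years)
  a <- truth$alpha_fn(grid$ses, grid$year)
  b <- truth$beta_fn(grid$ses, grid$year)
  if (!all(is.finite(a)) || any(a <= 0)) {
    stop("alpha_fn must return strictly positive finite values over the covariate ranges")
  }
  if (!all(is.finite(b)) || any(b <= 0)) {
    stop("beta_fn must return strictly positive finite values over the covariate ranges")
  }
  if (!is.null(truth$refugee_truth)) validate_ground_truth(truth$refugee_truth)
  invisible(truth)
}

#' Default ground truth calibrated to observed rural-South-Africa magnitudes
#'
#' Returns a smooth truth with weak SES dependence and a mild year trend:
#' shape linear in SES and year, scale constant. The curve peaks between ages
#' 26 and 29 with a peak rate of about 0.12, matching the magnitudes of
#' published empirical fertility-rate tables for the emulated surveillance
#' population (roughly 0.10-0.13 for ages 20-30). Note that a Gamma density
#' with that peak height and location is necessarily narrow (shape around
#' 66, scale 0.42 years), since its peak value is approximately
#' `0.4 / (sqrt(shape) * scale)`.
#'
#' @param rows_per_year woman-year rows per census year; the default gives a
#'   total of 224,640 rows, the scale of the emulated census database.
#' @return object of class `ground_truth`.
#' @examples
#' truth <- make_default_truth(rows_per_year = 1000)
#' obs <- simulate_population(truth, seed = 1)
#' head(obs)
#' @export
make_default_truth <- function(rows_per_year = 37440L) {
  ground_truth(
    alpha_fn = function(ses, year) 66 + 1.2 * (ses - 2.5) + 0.35 * (year - 2006) / 2,
    beta_fn = function(ses, year) rep_len(0.42, length(ses)),
    age_range = c(10, 55),
    ses_range = c(1, 4),
    years = seq(2001, 2011, by = 2),
    cohort_sizes = rows_per_year
  )
}

#' True fertility rate implied by a ground truth
#'
#' @param truth a `ground_truth`.
#' @param age,ses,year vectors (recycled to a common length).
#' @return clamped Gamma-density rates in `[0, 1)`.
#' @export
true_rate <- function(truth, age, ses, year) {
  n <- max(length(age), length(ses), length(year))
  age <- rep_len(age, n); ses <- rep_len(ses, n); year <- rep_len(year, n)
  clamp01(stats::dgamma(age, shape = truth$alpha_fn(ses, year),
                        scale = truth$beta_fn(ses, year)))
}

#' Simulate a woman-year observation table
#'
#' For each census year, draws `cohort_sizes` women with ages and SES from
#' the truth's sampling distributions (uniform by default), then draws the
#' live-birth indicator `y ~ Bernoulli(rate)` where the rate is the clamped
#' Gamma density at the woman's age given her covariates. Women are redrawn
#' independently each year; woman-years are treated as independent
#' observations. The same truth and seed always produce an identical table.
#'
#' @param truth a `ground_truth`.
#' @param seed integer seed; the caller's RNG state is preserved.
#' @return a `data.frame` of class `obs_table` with columns `woman_id`,
#'   `year`, `age`, `ses`, `refugee`, `education`, `y`.
#' @export
simulate_population <- function(truth, seed) {
  validate_ground_truth(truth)
  stopifnot(length(seed) == 1, is.finite(seed))
  with_seed(seed, {
    per_year <- lapply(seq_along(truth$years), function(j) {
      yr <- truth$years[j]
      n <- truth$cohort_sizes[j]
      age <- if (is.null(truth$age_sampler)) {
        stats::runif(n, truth$age_range[1], truth$age_range[2])
      } else truth$age_sampler(n)
      ses <- if (is.null(truth$ses_sampler)) {
        stats::runif(n, truth$ses_range[1], truth$ses_range[2])
      } else truth$ses_sampler(n)
      refugee <- stats::rbinom(n, 1L, truth$refugee_fraction)
      rate <- numeric(n)
      non_ref <- refugee == 0L | is.null(truth$refugee_truth)
      rate[non_ref] <- true_rate(truth, age[non_ref], ses[non_ref], yr)
      if (!is.null(truth$refugee_truth) && any(!non_ref)) {
        rate[!non_ref] <- true_rate(truth$refugee_truth,
                                    age[!non_ref], ses[!non_ref], yr)
      }
      n_clamped <- sum(stats::dgamma(age, shape = truth$alpha_fn(ses, yr),
                                     scale = truth$beta_fn(ses, yr)) > 1)
      if (n_clamped > 0) {
        fg_log(sprintf("year %d: clamped %d rates above 1", yr, n_clamped),
               verbose = TRUE)
      }
      data.frame(
        woman_id = sprintf("W%d-%06d", yr, seq_len(n)),
        year = rep.int(as.integer(yr), n),
        age = age,
        ses = ses,
        refugee = refugee,
        education = sample(0:12, n, replace = TRUE),
        y = stats::rbinom(n, 1L, rate),
        stringsAsFactors = FALSE
      )
    })
    obs <- do.call(rbind, per_year)
    rownames(obs) <- NULL
    class(obs) <- c("obs_table", "data.frame")
    fg_log(sprintf("simulated %d woman-years over %d census years",
                   nrow(obs), length(truth$years)))
    obs
  })
}

#' Validate a woman-year observation table
#'
#' Checks the contract every downstream stage assumes: required columns
#' present; no missing age, SES or birth indicator; ages finite and
#' non-negative; `y` binary; each `(woman_id, year)` pair unique.
#'
#' @param obs a data.frame of woman-year rows.
#' @return `obs`, invisibly classed as `obs_table`.
#' @export
validate_obs_table <- function(obs) {
  need <- c("woman_id", "year", "age", "ses", "y")
  missing_cols <- setdiff(need, names(obs))
  if (length(missing_cols)) {
    stop("observation table lacks columns: ", paste(missing_cols, collapse = ", "))
  }
  if (anyNA(obs$age) || anyNA(obs$ses) || anyNA(obs$y)) {
    stop("age, ses and y must not contain missing values")
  }
  if (any(!is.finite(obs$age)) || any(obs$age < 0)) {
    stop("age must be finite and non-negative")
  }
  if (!all(obs$y %in% c(0, 1))) stop("y must be binary (0/1)")
  if (anyDuplicated(paste(obs$woman_id, obs$year, sep = "\r"))) {
    stop("duplicated (woman_id, year) pair")
  }
  if (!inherits(obs, "obs_table")) class(obs) <- c("obs_table", class(obs))
  invisible(obs)
}
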