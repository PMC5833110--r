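# Quantile binning of covariates and empirical rate computation. Observations
# are mapped to the midpoints of empirical-quantile intervals, and fertility
# per cell is the fraction of women in the cell with a live birth; the
# resulting table is the regression dataset for the per-slice Gamma fits.

#' Quantile bins for one covariate
#'
#' Edges are the empirical quantiles at probabilities `k/q` (linear
#' interpolation between order statistics, `stats::quantile` type 7). Each
#' value is assigned the midpoint `(lower + upper)/2` of its interval;
#' intervals are half-open `[lower, upper)` except the last, which is closed.
#' Duplicate edges produced by heavy ties are merged with a warning.
#'
#' @param values numeric vector, non-empty.
#' @param q number of quantile bins (>= 1).
#' @return object of class `quantile_bins` with `edges` and `midpoints`.
#' @examples
#' quantile_bin(c(1, 2, 3, 4), 2)  # edges 1, 2.5, 4; midpoints 1.75, 3.25
#' @export
quantile_bin <- function(values, q) {
  if (length(values) == 0) stop("cannot bin an empty vector")
  stopifnot(q >= 1, q == round(q), all(is.finite(values)))
  edges <- unname(stats::quantile(values, probs = seq(0, 1, length.out = q + 1),
                                  type = 7, names = FALSE))
  if (anyDuplicated(edges)) {
    warning("duplicate quantile edges from ties; merging affected bins")
    edges <- unique(edges)
  }
  if (length(edges) == 1) edges <- c(edges, edges)  # all values identical
  mid <- (edges[-length(edges)] + edges[-1]) / 2
  structure(list(q = as.integer(q), edges = edges, midpoints = mid),
            class = "quantile_bins")
}

#' Map values to their bin midpoints
#'
#' Values outside the edge range (e.g. held-out data in cross-validation)
#' are assigned to the nearest terminal bin.
#'
#' @param values numeric vector.
#' @param bins a `quantile_bins` object.
#' @return numeric vector of midpoints, same length as `values`.
#' @export
assign_bins <- function(values, bins) {
  stopifnot(inherits(bins, "quantile_bins"))
  idx <- findInterval(values, bins$edges, rightmost.closed = TRUE,
                      all.inside = TRUE)
  bins$midpoints[idx]
}

#' Binning specification for an observation table
#'
#' Builds quantile bins for age and SES (year is a discrete stratifier and is
#' never binned). Quantiles are pooled across years by default; `per_year`
#' computes separate edges within each census year.
#'
#' @param obs an observation table (see [validate_obs_table()]).
#' @param age_q,ses_q quantile counts; the defaults of 125 and 25 suit
#'   census-scale tables and should be re-selected per dataset with
#'   [select_model()].
#' @param per_year logical; compute quantiles within each year separately.
#' @return object of class `bin_spec`.
#' @export
bin_spec <- function(obs, age_q = 125, ses_q = 25, per_year = FALSE) {
  validate_obs_table(obs)
  if (per_year) {
    yrs <- sort(unique(obs$year))
    by_year <- lapply(yrs, function(yr) {
      sub <- obs[obs$year == yr, ]
      list(age = quantile_bin(sub$age, age_q), ses = quantile_bin(sub$ses, ses_q))
    })
    names(by_year) <- as.character(yrs)
    structure(list(per_year = TRUE, years = yrs, bins = by_year,
                   age_q = age_q, ses_q = ses_q), class = "bin_spec")
  } else {
    structure(list(per_year = FALSE,
                   bins = list(age = quantile_bin(obs$age, age_q),
                               ses = quantile_bin(obs$ses, ses_q)),
                   age_q = age_q, ses_q = ses_q), class = "bin_spec")
  }
}

bins_for_year <- function(spec, year) {
  if (!spec$per_year) return(spec$bins)
  b <- spec$bins[[as.character(year)]]
  if (is.null(b)) stop("no bins for year ", year, " in per-year bin spec")
  b
}

#' Empirical fertility rates per bin cell
#'
#' Assigns every woman-year to its (age-bin, SES-bin, year) cell and computes
#' trials, births and the empirical rate per occupied cell. Total trials and
#' births are conserved: they sum to the row and birth counts of `obs`.
#'
#' @param obs an observation table.
#' @param spec a `bin_spec` built from compatible covariates.
#' @return `data.frame` of class `binned_data` with columns `age_mid`,
#'   `ses_mid`, `year`, `n_trials`, `n_births`, `rate`.
#' @export
empirical_rates <- function(obs, spec) {
  validate_obs_table(obs)
  stopifnot(inherits(spec, "bin_spec"))
  if (spec$per_year) {
    parts <- lapply(sort(unique(obs$year)), function(yr) {
      sub <- obs[obs$year == yr, ]
      b <- bins_for_year(spec, yr)
      data.frame(age_mid = assign_bins(sub$age, b$age),
                 ses_mid = assign_bins(sub$ses, b$ses),
                 year = sub$year, y = sub$y)
    })
    df <- do.call(rbind, parts)
  } else {
    df <- data.frame(age_mid = assign_bins(obs$age, spec$bins$age),
                     ses_mid = assign_bins(obs$ses, spec$bins$ses),
                     year = obs$year, y = obs$y)
  }
  dt <- data.table::as.data.table(df)
  agg <- dt[, list(n_trials = .N, n_births = sum(y)),
            by = c("age_mid", "ses_mid", "year")]
  data.table::setorderv(agg, c("year", "ses_mid", "age_mid"))
  out <- as.data.frame(agg)
  out$rate <- out$n_births / out$n_trials
  class(out) <- c("binned_data", "data.frame")
  fg_log(sprintf("binned %d rows into %d occupied cells", nrow(obs), nrow(out)))
  out
}
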