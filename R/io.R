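# Delimited-text interchange. All outputs are headered CSV; files written by
# the pipeline carry comment lines recording the package version, the seed
# and a hash of the configuration, so identical config + seed reproduce
# byte-identical files.

fertgp_version <- function() {
  as.character(utils::packageVersion("fertgp"))
}

#' Hash of a configuration object
#'
#' MD5 of the deparsed object; used in output file headers so runs are
#' auditable.
#'
#' @param config any R object (typically a [fit_config()]).
#' @return character MD5 hash.
#' @export
config_hash <- function(config) {
  tf <- tempfile()
  on.exit(unlink(tf))
  writeLines(deparse(config, control = "all"), tf)
  unname(tools::md5sum(tf))
}

write_headered_csv <- function(df, path, seed = NULL, config = NULL) {
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(sprintf("# fertgp %s", fertgp_version()), con)
  if (!is.null(seed)) writeLines(sprintf("# seed: %d", as.integer(seed)), con)
  if (!is.null(config)) writeLines(sprintf("# config_hash: %s", config_hash(config)), con)
  utils::write.csv(df, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

read_headered_csv <- function(path) {
  utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
}

#' Write / read a woman-year observation table
#'
#' Comma-separated UTF-8 text, one row per woman-year, columns exactly
#' `woman_id, year, age, ses, refugee, education, y`, preceded by `#`
#' comment lines recording provenance.
#'
#' @param obs an observation table.
#' @param path file path.
#' @param seed,config optional provenance recorded in the header.
#' @return the path (write) or an `obs_table` (read).
#' @export
write_obs_table <- function(obs, path, seed = NULL, config = NULL) {
  validate_obs_table(obs)
  cols <- c("woman_id", "year", "age", "ses", "refugee", "education", "y")
  for (c0 in cols) if (is.null(obs[[c0]])) obs[[c0]] <- NA
  write_headered_csv(obs[, cols], path, seed = seed, config = config)
}

#' @rdname write_obs_table
#' @export
read_obs_table <- function(path) {
  obs <- read_headered_csv(path)
  validate_obs_table(obs)
  class(obs) <- c("obs_table", "data.frame")
  obs
}

#' Export a binned dataset
#'
#' Columns `age_mid, ses_mid, year, n_trials, n_births, rate`.
#'
#' @param binned a `binned_data` table from [empirical_rates()].
#' @param path file path.
#' @param seed,config optional provenance recorded in the header.
#' @return the path, invisibly.
#' @export
write_binned_data <- function(binned, path, seed = NULL, config = NULL) {
  stopifnot(inherits(binned, "binned_data"))
  write_headered_csv(binned[, c("age_mid", "ses_mid", "year",
                                "n_trials", "n_births", "rate")],
                     path, seed = seed, config = config)
}

#' Fitted fertility curves over age and over SES
#'
#' Evaluates a fitted model on the standard presentation slices: rate over
#' age at fixed SES values per year, and rate over SES at fixed ages per
#' year.
#'
#' @param model a `fertility_model`.
#' @param ses_values SES values for the over-age curves (defaults span the
#'   low, middle and high range of the index).
#' @param ages ages for the over-SES curves (defaults 18, 28, 38).
#' @param years years to evaluate (default: the model's training years).
#' @param age_grid,ses_grid evaluation grids.
#' @return list of two data.frames `over_age` and `over_ses`.
#' @export
fertility_curves <- function(model,
                             ses_values = c(1.445, 2.46, 3.44),
                             ages = c(18, 28, 38),
                             years = NULL,
                             age_grid = seq(10, 55, by = 0.5),
                             ses_grid = seq(1, 4, by = 0.05)) {
  years <- years %||% model$years
  over_age <- do.call(rbind, lapply(years, function(yr) {
    do.call(rbind, lapply(ses_values, function(s) {
      data.frame(age = age_grid, ses = s, year = yr,
                 rate = predict_fertility(model, age_grid, s, yr))
    }))
  }))
  over_ses <- do.call(rbind, lapply(years, function(yr) {
    do.call(rbind, lapply(ages, function(a) {
      data.frame(age = a, ses = ses_grid, year = yr,
                 rate = predict_fertility(model, a, ses_grid, yr))
    }))
  }))
  list(over_age = over_age, over_ses = over_ses)
}

#' Export bootstrap bands as delimited text
#'
#' @param bands a `bootstrap_bands` object.
#' @param path file path.
#' @param config optional config recorded in the header.
#' @return the path, invisibly.
#' @export
write_bootstrap_bands <- function(bands, path, config = NULL) {
  stopifnot(inherits(bands, "bootstrap_bands"))
  df <- cbind(bands$grid, as.data.frame(t(bands$bands)))
  write_headered_csv(df, path, seed = bands$seed, config = config)
}
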