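# CSV and config I/O.  Dialect everywhere: comma-separated, header row,
# UTF-8, "." decimal, no thousands separators.

#' Read an annual episode series from CSV
#'
#' Accepts `year,count,population` or `year,rate_per_100k,population`
#' (rates are converted to counts with a warning, since fitting needs
#' counts).  Validation errors name the offending row or year.
#'
#' @param path CSV file path.
#' @return An [annual_series()] tibble.
#' @export
read_annual_series <- function(path) {
  if (!file.exists(path)) abort(sprintf("File not found: %s", path))
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  annual_series(df)
}

#' Write an annual episode series to CSV
#'
#' @param series An [annual_series()] tibble.
#' @param path Output path; header `year,count,population`.
#' @return `path`, invisibly.
#' @export
write_annual_series <- function(series, path) {
  series <- annual_series(series)
  readr::write_csv(series[c("year", "count", "population")], path)
  invisible(path)
}

#' Read a population trajectory from CSV (`year,population`)
#'
#' @param path CSV file path.
#' @return Tibble `year, population`.
#' @export
read_population_series <- function(path) {
  if (!file.exists(path)) abort(sprintf("File not found: %s", path))
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  validate_population_series(df)
}

#' Write a population trajectory to CSV
#'
#' Populations are exported rounded half-up to whole persons.
#'
#' @param population Tibble `year, population`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_population_series <- function(population, path) {
  population <- validate_population_series(population)
  population$population <- round_half_up(population$population)
  readr::write_csv(population, path)
  invisible(path)
}

#' Default pipeline configuration
#'
#' All defaults mirror the study set-up the package emulates: the 2020
#' pandemic year excluded from fitting, 1000 bootstrap iterations, an
#' 18-year projection horizon 2023--2040, three demographic scenarios with
#' net migration 0 / 30,000 / 60,000 persons per year, and the
#' hospitalisation cost block (2-day stays at 500 SGD/day in 2013 prices,
#' 2022 reference year, fx 1.33 SGD/USD, 40 per 100,000 benchmark).
#'
#' @return Nested list understood by [run_pipeline()].
#' @export
default_pipeline_config <- function() {
  list(
    input = list(series_csv = NULL, population_csvs = NULL,
                 preset = "paper_like"),
    seed = 1L,
    excluded_years = 2020L,
    max_changepoints = 3L,
    min_segment_len = 3L,
    n_bootstrap = 1000L,
    bootstrap_type = "parametric",
    projection_years = c(2023L, 2040L),
    scenarios = NULL,
    cost = list(unit = "hospitalisation",
                length_of_stay_days = 2,
                cost_per_day_sgd_2013 = 500,
                inflation_factor_2013_to_2022 = 1.11665,
                ed_fees_sgd = c(120, 128, 121, 126, 120, 121, 122),
                fx_sgd_per_usd = 1.33,
                benchmark_rate_per_100k = 40,
                discount_rate = 0,
                rounding = "half_up",
                currency = "USD"),
    output_dir = NULL
  )
}

#' Read a pipeline configuration file (YAML)
#'
#' Values in the file override [default_pipeline_config()] recursively;
#' anything omitted keeps its default.
#'
#' @param path YAML file path.
#' @return Config list.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) abort(sprintf("Config file not found: %s", path))
  user <- yaml::read_yaml(path)
  merge_config(default_pipeline_config(), user)
}

merge_config <- function(base, user) {
  for (nm in names(user)) {
    if (is.list(user[[nm]]) && is.list(base[[nm]]) &&
        !is.null(names(user[[nm]]))) {
      base[[nm]] <- merge_config(base[[nm]], user[[nm]])
    } else {
      base[[nm]] <- user[[nm]]
    }
  }
  base
}

# Stable md5 of an R object via its canonical YAML rendering.
config_hash <- function(x) {
  f <- tempfile(fileext = ".yaml")
  on.exit(unlink(f))
  yaml::write_yaml(x, f)
  unname(tools::md5sum(f))
}
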