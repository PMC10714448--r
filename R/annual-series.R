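# Annual episode series: the common tabular currency of the package.
# A valid series is a tibble with consecutive integer `year`, non-negative
# integer `count`, positive `population`, and a derived `rate_per_100k`.

#' Build and validate an annual episode series
#'
#' Assembles the package's standard series tibble from a data frame with
#' `year`, `count` (or `rate_per_100k`) and `population` columns, checking
#' the invariants every downstream stage relies on: consecutive years,
#' non-negative integer counts, positive populations.  A series supplied in
#' rate form is converted to counts via
#' `round_half_up(rate_per_100k * population / 1e5)` with a warning, since
#' Poisson fitting needs counts.
#'
#' @param data Data frame with columns `year`, `population` and either
#'   `count` or `rate_per_100k`.
#' @return A tibble with columns `year`, `count`, `population`,
#'   `rate_per_100k` (one row per year, years ascending and consecutive).
#' @examples
#' annual_series(data.frame(year = 2017:2019, count = c(10, 12, 11),
#'                          population = 1e6))
#' @export
annual_series <- function(data) {
  stopifnot(is.data.frame(data))
  cols <- names(data)
  if (!all(c("year", "population") %in% cols)) {
    abort("`data` must have `year` and `population` columns.")
  }
  has_count <- "count" %in% cols
  has_rate <- "rate_per_100k" %in% cols
  if (!has_count && !has_rate) {
    abort("`data` must have a `count` or `rate_per_100k` column.")
  }

  out <- as_tibble(data)
  out <- out[order(out$year), ]
  check_years_consecutive(out$year)
  bad_pop <- which(!is.finite(out$population) | out$population <= 0)
  if (length(bad_pop)) {
    abort(sprintf("Non-positive population in row %d (year %s).",
                  bad_pop[1], out$year[bad_pop[1]]))
  }

  if (!has_count) {
    warn("Series supplied as rates per 100,000; converting to counts.")
    out$count <- round_half_up(out$rate_per_100k * out$population / 1e5)
  }
  bad <- which(!is_whole(out$count) | out$count < 0)
  if (length(bad)) {
    abort(sprintf("Counts must be non-negative integers; row %d (year %s) has %s.",
                  bad[1], out$year[bad[1]], format(out$count[bad[1]])))
  }
  out$count <- round(out$count)
  out$rate_per_100k <- out$count / out$population * 1e5
  out[c("year", "count", "population", "rate_per_100k")]
}

check_years_consecutive <- function(years) {
  if (anyNA(years) || !all(is_whole(years))) {
    abort("Years must be whole numbers.")
  }
  if (length(years) >= 2) {
    gaps <- which(diff(years) != 1)
    if (length(gaps)) {
      if (diff(years)[gaps[1]] < 1) abort("Duplicated year in series.")
      abort(sprintf("Years must be consecutive: missing year %d.",
                    as.integer(years[gaps[1]] + 1)))
    }
  }
  invisible(years)
}

# Internal: validate a population series tibble (year, population).
validate_population_series <- function(population) {
  stopifnot(is.data.frame(population),
            all(c("year", "population") %in% names(population)))
  population <- as_tibble(population)[c("year", "population")]
  population <- population[order(population$year), ]
  check_years_consecutive(population$year)
  if (any(!is.finite(population$population) | population$population <= 0)) {
    abort("All populations must be positive.")
  }
  population
}
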