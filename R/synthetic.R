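# Synthetic-data generators: demographic scenarios, piecewise log-linear
# ground-truth rates, Poisson count realisations, single-year shocks.
# Everything downstream (fitting, projection, costing) is tested against
# series produced here, where the truth is known by construction.

#' Define a demographic scenario
#'
#' A scenario is a simple annual recurrence for resident population:
#' `P(y+1) = P(y) * (1 + natural_growth_rate) + net_migration`, evaluated
#' yearly from `base_year` through `horizon_end`.  The recurrence is a
#' deliberately reduced stand-in for cohort-component projections: scenario
#' comparisons here only need trajectories ordered by migration level.  The
#' three conventional variants hold natural growth fixed (low-fertility
#' regime) and set net migration to 0, 30,000 or 60,000 persons per year.
#'
#' @param name Scenario label.
#' @param base_year Calendar year at which `base_population` is anchored.
#' @param base_population Resident population in `base_year` (> 0).
#' @param natural_growth_rate Per-year fractional growth from the balance of
#'   births and deaths (may be negative).
#' @param net_migration Persons added per year (>= 0).
#' @param horizon_end Last calendar year of the trajectory (> `base_year`).
#' @return A `scenario_spec` object (a named list).
#' @examples
#' scenario_spec("base", 2020, 4e6, 0.001, 30000, 2040)
#' @export
scenario_spec <- function(name, base_year, base_population,
                          natural_growth_rate, net_migration, horizon_end) {
  if (!is.numeric(base_population) || base_population <= 0) {
    abort("`base_population` must be > 0.")
  }
  if (horizon_end <= base_year) abort("`horizon_end` must exceed `base_year`.")
  if (net_migration < 0) abort("`net_migration` must be >= 0.")
  structure(
    list(name = as.character(name),
         base_year = as.integer(base_year),
         base_population = as.double(base_population),
         natural_growth_rate = as.double(natural_growth_rate),
         net_migration = as.double(net_migration),
         horizon_end = as.integer(horizon_end)),
    class = "scenario_spec"
  )
}

#' @export
print.scenario_spec <- function(x, ...) {
  cat(sprintf(
    "<scenario_spec '%s'>\n  %d: %s persons; growth %+.3f%%/yr; migration %s/yr; to %d\n",
    x$name, x$base_year, format(x$base_population, big.mark = ","),
    100 * x$natural_growth_rate, format(x$net_migration, big.mark = ","),
    x$horizon_end))
  invisible(x)
}

#' Generate a population trajectory from a scenario
#'
#' Evaluates the scenario recurrence deterministically, one step per year.
#' Populations are carried as real numbers internally so no rounding drift
#' compounds through the recurrence; use `round_half_up()` on export if
#' whole persons are needed.
#'
#' @param scenario A [scenario_spec()].
#' @return Tibble with columns `year`, `population`, one row per year from
#'   `base_year` to `horizon_end`.
#' @examples
#' generate_population(scenario_spec("closed", 2020, 4e6, 0, 0, 2025))
#' @export
generate_population <- function(scenario) {
  stopifnot(inherits(scenario, "scenario_spec"))
  years <- scenario$base_year:scenario$horizon_end
  pop <- numeric(length(years))
  pop[1] <- scenario$base_population
  for (i in seq_along(years)[-1]) {
    pop[i] <- pop[i - 1] * (1 + scenario$natural_growth_rate) +
      scenario$net_migration
    if (pop[i] <= 0) {
      abort(sprintf("Scenario '%s' implies non-positive population in %d.",
                    scenario$name, years[i]))
    }
  }
  tibble(year = years, population = pop)
}

#' Define piecewise log-linear ground-truth rates
#'
#' The generator's truth mirrors the fitted model: within each segment the
#' per-person rate is `exp(intercept + slope * (year - segment_start))`,
#' with each segment anchored at its own first year.  `change_years` are the
#' first years of segments 2..k+1.
#'
#' @param start_year First year the rate structure covers.
#' @param end_year Last year covered.
#' @param change_years Ordered vector of change years strictly inside
#'   `(start_year, end_year]`; may be empty.
#' @param intercepts Log per-person rate at each segment's own start year
#'   (length = number of segments).
#' @param slopes Per-year change in log rate, one per segment.
#' @return A `piecewise_rates` object.
#' @examples
#' piecewise_rates(1994, 2019, change_years = 2003,
#'                 intercepts = log(c(120, 80) / 1e5), slopes = c(-0.04, 0))
#' @export
piecewise_rates <- function(start_year, end_year, change_years = integer(),
                            intercepts, slopes) {
  k <- length(change_years)
  if (length(intercepts) != k + 1 || length(slopes) != k + 1) {
    abort("Need one (intercept, slope) pair per segment: segments = changes + 1.")
  }
  if (k > 0) {
    if (is.unsorted(change_years, strictly = TRUE)) {
      abort("`change_years` must be strictly increasing.")
    }
    if (any(change_years <= start_year | change_years > end_year)) {
      abort("`change_years` must lie strictly inside the series span.")
    }
  }
  x <- structure(
    list(start_year = as.integer(start_year),
         end_year = as.integer(end_year),
         change_years = as.integer(change_years),
         intercepts = as.double(intercepts),
         slopes = as.double(slopes)),
    class = "piecewise_rates"
  )
  r <- true_rate(x, start_year:end_year)
  if (any(!is.finite(r) & r > 0) || any(r >= 1)) {
    abort("Implied per-person rate must stay below 1 over the span.")
  }
  x
}

#' True per-person rate of a piecewise structure at given years
#'
#' @param rates A [piecewise_rates()] object.
#' @param years Years at which to evaluate (within the span).
#' @return Numeric vector of per-person rates.
#' @export
true_rate <- function(rates, years) {
  stopifnot(inherits(rates, "piecewise_rates"))
  if (any(years < rates$start_year | years > rates$end_year)) {
    abort("Years outside the rate structure's span.")
  }
  starts <- c(rates$start_year, rates$change_years)
  seg <- findInterval(years, starts)
  exp(rates$intercepts[seg] + rates$slopes[seg] * (years - starts[seg]))
}

#' Draw Poisson annual counts from ground-truth rates
#'
#' Realises `count[y] ~ Poisson(population[y] * rate[y])` independently per
#' year.  Identical `(rates, population, seed)` give a bit-identical series.
#'
#' @param rates A [piecewise_rates()] covering all population years.
#' @param population Tibble `year, population` (e.g. from
#'   [generate_population()]).
#' @param seed Integer RNG seed.
#' @return An [annual_series()] tibble.
#' @examples
#' pop <- generate_population(scenario_spec("s", 1994, 3.5e6, 0.005, 0, 2019))
#' generate_counts(piecewise_rates(1994, 2019, intercepts = log(8e-4),
#'                                 slopes = 0), pop, seed = 1)
#' @export
generate_counts <- function(rates, population, seed) {
  population <- validate_population_series(population)
  if (rates$start_year > min(population$year) ||
      rates$end_year < max(population$year)) {
    abort("Rate structure must span all population years.")
  }
  mu <- population$population * true_rate(rates, population$year)
  if (any(!is.finite(mu))) abort("Non-finite Poisson mean implied.")
  if (any(mu >= population$population)) {
    abort("Poisson mean exceeds population: per-person rate >= 1.")
  }
  counts <- withr_seed(seed, rpois(length(mu), mu))
  annual_series(tibble(year = population$year, count = counts,
                       population = population$population))
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`.
withr_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

#' Redraw selected years at a reduced Poisson mean (pandemic-style shock)
#'
#' Emulates a transient utilisation collapse (such as the ~50% fall in
#' admission and attendance rates during the 2020 pandemic year): counts in
#' `shock_years` are redrawn from `Poisson(multiplier * original count)`,
#' taking the observed count as the local mean; other years are untouched.
#' With `multiplier = 1` the series is returned unchanged (no resampling).
#'
#' @param series An [annual_series()] tibble.
#' @param shock_years Years to shock (must be present in the series).
#' @param multiplier Mean multiplier in `[0, 1]`.
#' @param seed Integer RNG seed for the redraw.
#' @return The shocked series as an [annual_series()] tibble.
#' @export
inject_shock <- function(series, shock_years, multiplier, seed) {
  series <- annual_series(series)
  unknown <- setdiff(shock_years, series$year)
  if (length(unknown)) {
    abort(sprintf("Shock year(s) not in series: %s.",
                  paste(unknown, collapse = ", ")))
  }
  if (multiplier < 0 || multiplier > 1) {
    abort("`multiplier` must be in [0, 1].")
  }
  if (multiplier == 1) return(series)
  idx <- match(shock_years, series$year)
  new_counts <- if (multiplier == 0) {
    rep(0L, length(idx))
  } else {
    withr_seed(seed, rpois(length(idx), multiplier * series$count[idx]))
  }
  series$count[idx] <- new_counts
  annual_series(series[c("year", "count", "population")])
}

#' Paper-like synthetic preset: series, truth and scenario populations
#'
#' One call that sets up a complete synthetic study: a 1994--2020
#' hospitalisation-like series (population growing 3.5M to ~4.0M, rates near
#' 80 per 100,000 with one change point in 2003 where an initial decline
#' flattens to slow growth, and a 50% shock in 2020), plus three projection
#' scenario populations (net migration 0 / 30,000 / 60,000 per year, shared
#' natural growth) extending to 2040.
#'
#' @param seed Integer seed controlling the Poisson draws.
#' @param shock_multiplier Mean multiplier applied to the 2020 count.
#' @return List with elements `series` (annual series incl. the shocked
#'   2020), `truth` (the [piecewise_rates()] used), `shock_year`,
#'   `scenarios` (list of [scenario_spec()]), and `populations` (named list
#'   of scenario population tibbles covering 2020--2040).
#' @examples
#' preset <- synthetic_preset(seed = 1)
#' head(preset$series)
#' @export
synthetic_preset <- function(seed = 1L, shock_multiplier = 0.5) {
  hist_scenario <- scenario_spec("historical", 1994, 3.5e6,
                                 natural_growth_rate = 0.0015,
                                 net_migration = 15000, horizon_end = 2020)
  hist_pop <- generate_population(hist_scenario)
  truth <- piecewise_rates(
    1994, 2020, change_years = 2003,
    intercepts = log(c(115, 80) / 1e5),
    slopes = c(-0.04, log(1.017))
  )
  series <- generate_counts(truth, hist_pop, seed = seed)
  series <- inject_shock(series, 2020, shock_multiplier,
                         seed = derive_seed(seed, 2020))

  base_pop_2020 <- hist_pop$population[hist_pop$year == 2020]
  scenarios <- list(
    scenario_spec("low-migration", 2020, base_pop_2020, 0.0015, 0, 2040),
    scenario_spec("base", 2020, base_pop_2020, 0.0015, 30000, 2040),
    scenario_spec("high-migration", 2020, base_pop_2020, 0.0015, 60000, 2040)
  )
  populations <- lapply(scenarios, generate_population)
  names(populations) <- vapply(scenarios, `[[`, "", "name")

  list(series = series, truth = truth, shock_year = 2020L,
       scenarios = scenarios, populations = populations)
}
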