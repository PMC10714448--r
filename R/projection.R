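# Projection of future episode counts: each bootstrap draw (y0, b0, b1) of
# the final stable trend is combined with a population trajectory via
#   N(y) = P_y * exp(b0 + b1 * (y - y0)),
# and per-year / period-total credible intervals are percentile summaries
# across draws.  Period totals are computed per draw before taking
# percentiles, never by summing per-year percentiles.

#' Project episode counts for one (y0, beta0, beta1) draw
#'
#' Evaluates `N(y) = P_y * exp(beta0 + beta1 * (y - y0))` over the requested
#' years; `y0` anchors the trend (at `y = y0` the projection depends only on
#' `beta0` and the population).  Values are kept fractional — rounding to
#' whole episodes happens only in final reports.
#'
#' @param draw Named list or one-row data frame with `y0`, `beta0`, `beta1`.
#' @param population Tibble `year, population` covering all `years`.
#' @param years Integer vector of projection years.
#' @return Tibble `year, episodes`.
#' @examples
#' pop <- tibble::tibble(year = 2023:2026, population = 1e6)
#' project_draw(list(y0 = 2019, beta0 = log(8e-4), beta1 = log(1.017)),
#'              pop, 2023:2026)
#' @export
project_draw <- function(draw, population, years) {
  population <- validate_population_series(population)
  idx <- match(years, population$year)
  if (anyNA(idx)) {
    abort(sprintf("Population does not cover projection year(s): %s.",
                  paste(years[is.na(idx)], collapse = ", ")))
  }
  rate <- exp(draw$beta0 + draw$beta1 * (years - draw$y0))
  if (any(rate >= 1)) {
    abort("Projected per-person rate >= 1: implausible extrapolation.")
  }
  tibble(year = as.integer(years),
         episodes = population$population[idx] * rate)
}

#' Summarise projected episodes across bootstrap draws
#'
#' Applies [project_draw()] to every draw and reports per-year medians with
#' 2.5th/97.5th percentile credible bounds, plus the period total summarised
#' from per-draw sums over the projection years.
#'
#' @param draws A [bootstrap_fit()] result (or any object whose `tidy()`
#'   has columns `y0`, `beta0`, `beta1`).
#' @param population Tibble `year, population` covering the years.
#' @param years Projection years (default 2023:2040, an 18-year horizon).
#' @param scenario Scenario label carried into the summary.
#' @return A `projection_summary` object: per-year table (via `tidy()`),
#'   period totals (via `glance()`), and the retained draws-by-years
#'   trajectory matrix in `$draws_per_year`.
#' @examples
#' preset <- synthetic_preset(seed = 1)
#' fit <- fit_segmented_poisson(preset$series, excluded_years = 2020,
#'                              max_changepoints = 1)
#' draws <- bootstrap_fit(preset$series, fit, n_iterations = 50, seed = 7)
#' summarize_projection(draws, preset$populations$base, scenario = "base")
#' @export
summarize_projection <- function(draws, population, years = 2023:2040,
                                 scenario = "base") {
  draw_tbl <- if (inherits(draws, "bootstrap_draws")) draws$draws
              else as_tibble(draws)
  if (nrow(draw_tbl) < 2) abort("Need at least 2 draws to summarise.")
  population <- validate_population_series(population)
  years <- as.integer(years)

  # iterations x years trajectory matrix
  traj <- vapply(seq_len(nrow(draw_tbl)), function(i) {
    tryCatch(
      project_draw(draw_tbl[i, ], population, years)$episodes,
      error = function(e) {
        abort(sprintf("Draw %d failed to project: %s", i, conditionMessage(e)))
      })
  }, numeric(length(years)))
  traj <- t(traj)

  per_year <- tibble(
    year = years,
    median_episodes = apply(traj, 2, median),
    ci_low = apply(traj, 2, quantile, probs = 0.025, names = FALSE),
    ci_high = apply(traj, 2, quantile, probs = 0.975, names = FALSE)
  )
  totals <- rowSums(traj)
  structure(
    list(scenario = scenario, years = years, by_year = per_year,
         total_median = median(totals),
         total_ci_low = quantile(totals, 0.025, names = FALSE),
         total_ci_high = quantile(totals, 0.975, names = FALSE),
         draws_per_year = traj, draw_totals = totals),
    class = "projection_summary"
  )
}

#' @describeIn summarize_projection Per-year projected episodes with 95%
#'   credible bounds.
#' @param x,object A `projection_summary`.
#' @param ... Unused.
#' @export
tidy.projection_summary <- function(x, ...) {
  dplyr::mutate(x$by_year, scenario = x$scenario, .before = 1)
}

#' @describeIn summarize_projection One-row period totals (median and 95%
#'   credible bounds of the per-draw period sums).
#' @export
glance.projection_summary <- function(x, ...) {
  tibble(scenario = x$scenario,
         year_first = min(x$years), year_last = max(x$years),
         total_median = x$total_median,
         total_ci_low = x$total_ci_low, total_ci_high = x$total_ci_high,
         n_draws = nrow(x$draws_per_year))
}

#' @export
print.projection_summary <- function(x, ...) {
  cat(sprintf(
    "<projection_summary '%s'> %d-%d: total %s (95%% CI %s-%s) episodes\n",
    x$scenario, min(x$years), max(x$years),
    format(round_half_up(x$total_median), big.mark = ","),
    format(round_half_up(x$total_ci_low), big.mark = ","),
    format(round_half_up(x$total_ci_high), big.mark = ",")))
  invisible(x)
}

#' @describeIn summarize_projection Median projection with 95% credible
#'   ribbon.
#' @export
autoplot.projection_summary <- function(object, ...) {
  ggplot2::ggplot(object$by_year, ggplot2::aes(x = .data$year)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$ci_low,
                                      ymax = .data$ci_high),
                         fill = "steelblue", alpha = 0.25) +
    ggplot2::geom_line(ggplot2::aes(y = .data$median_episodes),
                       colour = "steelblue") +
    ggplot2::labs(x = "Year", y = "Projected episodes",
                  title = paste0("Projected episodes (", object$scenario, ")"))
}

#' Project the same draws under several demographic scenarios
#'
#' Re-uses one set of bootstrap draws across scenario population
#' trajectories, so the population is the only varying factor; projected
#' totals therefore order with the scenarios' population sizes (e.g. with
#' net migration level when natural growth is shared).
#'
#' @param draws A [bootstrap_fit()] result.
#' @param scenario_populations Named list of `year, population` tibbles.
#' @param years Projection years.
#' @return List of `projection_summary`, one per scenario, in input order.
#' @export
compare_scenarios <- function(draws, scenario_populations,
                              years = 2023:2040) {
  stopifnot(is.list(scenario_populations), length(scenario_populations) >= 1)
  nms <- names(scenario_populations) %||%
    paste0("scenario_", seq_along(scenario_populations))
  purrr::imap(setNames(scenario_populations, nms), function(pop, nm) {
    missing_years <- setdiff(as.integer(years), pop$year)
    if (length(missing_years)) {
      abort(sprintf("Scenario '%s' population does not cover year(s) %s.",
                    nm, paste(missing_years, collapse = ", ")))
    }
    summarize_projection(draws, pop, years = years, scenario = nm)
  })
}
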