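# Cost-of-care estimation: per-episode unit costs (hospitalisation day-cost
# x length of stay; averaged ED attendance fees), a single configured
# SGD/USD exchange rate, and benchmark-capped savings.  All headline costs
# are reference-year currency; no discounting unless asked for.

#' Per-episode hospitalisation unit cost
#'
#' Builds the hospitalisation unit cost as length of stay times the daily
#' ward cost, inflated from its base year to the reference year.  The
#' inflation step is applied to the stay total with the factor carried at
#' full precision; the SGD amount is then rounded to cents by the chosen
#' rule (`half_up` default; `truncate` provided because published
#' cost figures are sometimes truncated rather than rounded).  The USD view
#' divides the rounded SGD amount by the configured exchange rate and
#' rounds half-up to cents.
#'
#' @param length_of_stay_days Average stay per episode (days).
#' @param cost_per_day Daily cost in base-year currency (SGD).
#' @param inflation_factor Multiplier from the base year to the reference
#'   year (default 1.11665, i.e. 2013 to 2022 SGD: a 500 SGD day costs
#'   558.33 SGD and a 2-day episode 1116.65 SGD).
#' @param fx_sgd_per_usd SGD per USD (default 1.33, 2022).
#' @param rounding `"half_up"` or `"truncate"` for the SGD cents rounding.
#' @param reference_year Currency reference year label.
#' @return A `unit_cost` object with `$sgd` and `$usd` amounts and a
#'   `$derivation` record of the inputs.
#' @examples
#' hospitalisation_unit_cost()  # SGD 1116.65, USD 839.59
#' @export
hospitalisation_unit_cost <- function(length_of_stay_days = 2,
                                      cost_per_day = 500,
                                      inflation_factor = 1.11665,
                                      fx_sgd_per_usd = 1.33,
                                      rounding = c("half_up", "truncate"),
                                      reference_year = 2022) {
  rounding <- match.arg(rounding)
  stopifnot(length_of_stay_days > 0, cost_per_day > 0,
            inflation_factor > 0, fx_sgd_per_usd > 0)
  raw_sgd <- length_of_stay_days * cost_per_day * inflation_factor
  sgd <- switch(rounding,
                half_up = round_half_up(raw_sgd, 2),
                truncate = trunc_digits(raw_sgd, 2))
  usd <- round_half_up(sgd / fx_sgd_per_usd, 2)
  new_unit_cost("hospitalisation", sgd, usd, reference_year, fx_sgd_per_usd,
                derivation = list(length_of_stay_days = length_of_stay_days,
                                  cost_per_day = cost_per_day,
                                  inflation_factor = inflation_factor,
                                  rounding = rounding))
}

#' Per-episode emergency-department unit cost
#'
#' Averages the attendance fees of the contributing hospitals, rounding the
#' SGD mean half-up to whole dollars (fee schedules are quoted in whole
#' dollars); the USD view divides by the exchange rate and rounds half-up
#' to cents.
#'
#' @param fees Vector of per-attendance fees in SGD (non-empty, positive).
#' @param fx_sgd_per_usd SGD per USD.
#' @param reference_year Currency reference year label.
#' @return A `unit_cost` object.
#' @examples
#' ed_unit_cost(c(120, 128, 121, 126, 120, 121, 122))  # SGD 123, USD 92.48
#' @export
ed_unit_cost <- function(fees, fx_sgd_per_usd = 1.33, reference_year = 2022) {
  if (length(fees) == 0) abort("Fee list must be non-empty.")
  if (any(fees <= 0)) abort("All fees must be positive.")
  sgd <- round_half_up(mean(fees), 0)
  usd <- round_half_up(sgd / fx_sgd_per_usd, 2)
  new_unit_cost("ed_attendance", sgd, usd, reference_year, fx_sgd_per_usd,
                derivation = list(fees = fees))
}

new_unit_cost <- function(kind, sgd, usd, reference_year, fx, derivation) {
  structure(list(kind = kind, sgd = sgd, usd = usd,
                 reference_year = reference_year, fx_sgd_per_usd = fx,
                 derivation = derivation),
            class = "unit_cost")
}

#' @export
print.unit_cost <- function(x, ...) {
  cat(sprintf("<unit_cost %s> SGD %.2f = USD %.2f (%d %s, fx %.2f SGD/USD)\n",
              x$kind, x$sgd, x$usd, as.integer(x$reference_year),
              "reference year", x$fx_sgd_per_usd))
  invisible(x)
}

unit_amount <- function(unit_cost, currency = c("USD", "SGD")) {
  currency <- match.arg(currency)
  if (currency == "USD") unit_cost$usd else unit_cost$sgd
}

# Per-year discount factors anchored at the first projection year.
discount_factors <- function(years, discount_rate) {
  (1 + discount_rate)^-(years - years[1])
}

#' Total cost of projected episodes
#'
#' Multiplies each bootstrap draw's episode trajectory by the per-episode
#' unit cost; the headline total and its 95% credible bounds are
#' percentiles of the per-draw period costs.  No discounting by default.
#'
#' @param projection A [summarize_projection()] result.
#' @param unit_cost A [hospitalisation_unit_cost()] or [ed_unit_cost()].
#' @param currency `"USD"` (default) or `"SGD"`.
#' @param discount_rate Optional annual discount rate (default 0), applied
#'   relative to the first projection year.
#' @return A `cost_summary` object; `tidy()` gives the report rows.
#' @export
total_cost <- function(projection, unit_cost, currency = c("USD", "SGD"),
                       discount_rate = 0) {
  currency <- match.arg(currency)
  stopifnot(inherits(projection, "projection_summary"),
            inherits(unit_cost, "unit_cost"))
  amount <- unit_amount(unit_cost, currency)
  disc <- discount_factors(projection$years, discount_rate)
  per_draw <- as.vector(projection$draws_per_year %*% disc) * amount
  new_cost_summary(
    scenario = projection$scenario, currency = currency,
    total_cost = median(per_draw),
    ci_low = quantile(per_draw, 0.025, names = FALSE),
    ci_high = quantile(per_draw, 0.975, names = FALSE),
    unit_cost = unit_cost, discount_rate = discount_rate,
    per_draw_cost = per_draw)
}

#' Savings from capping episodes at a benchmark rate
#'
#' Costs only the episodes in excess of a benchmark rate per 100,000 (for
#' each draw and year, `max(0, N(y) - benchmark * P_y / 1e5)`), summarises
#' the per-draw savings by percentiles, and reports the headline percentage
#' reduction as `100 * savings_median / total_cost_median`.
#'
#' @param projection A [summarize_projection()] result.
#' @param population Tibble `year, population` covering the projection
#'   years (the denominators the benchmark applies to).
#' @param benchmark_rate_per_100k Cap in episodes per 100,000 per year
#'   (> 0).
#' @param unit_cost A `unit_cost` object.
#' @param currency `"USD"` or `"SGD"`.
#' @param discount_rate Optional annual discount rate (default 0).
#' @return A `cost_summary` with `savings`, its credible bounds,
#'   `reduction_pct`, and the underlying total-cost summary.
#' @export
benchmark_savings <- function(projection, population, benchmark_rate_per_100k,
                              unit_cost, currency = c("USD", "SGD"),
                              discount_rate = 0) {
  currency <- match.arg(currency)
  stopifnot(inherits(projection, "projection_summary"),
            benchmark_rate_per_100k > 0)
  population <- validate_population_series(population)
  idx <- match(projection$years, population$year)
  if (anyNA(idx)) {
    abort(sprintf("Population does not cover projection year(s) %s.",
                  paste(projection$years[is.na(idx)], collapse = ", ")))
  }
  amount <- unit_amount(unit_cost, currency)
  disc <- discount_factors(projection$years, discount_rate)
  cap <- benchmark_rate_per_100k * population$population[idx] / 1e5
  excess <- pmax(sweep(projection$draws_per_year, 2, cap, `-`), 0)
  savings_draw <- as.vector(excess %*% disc) * amount
  total_draw <- as.vector(projection$draws_per_year %*% disc) * amount
  savings <- median(savings_draw)
  total <- median(total_draw)
  new_cost_summary(
    scenario = projection$scenario, currency = currency,
    total_cost = total,
    ci_low = quantile(total_draw, 0.025, names = FALSE),
    ci_high = quantile(total_draw, 0.975, names = FALSE),
    unit_cost = unit_cost, discount_rate = discount_rate,
    per_draw_cost = total_draw,
    benchmark_rate = benchmark_rate_per_100k,
    savings = savings,
    savings_ci_low = quantile(savings_draw, 0.025, names = FALSE),
    savings_ci_high = quantile(savings_draw, 0.975, names = FALSE),
    reduction_pct = reduction_percent(savings, total),
    per_draw_savings = savings_draw)
}

#' Percentage cost reduction implied by a savings figure
#'
#' The headline reduction definition used throughout:
#' `100 * savings / total_cost`.
#'
#' @param savings Avoidable cost.
#' @param total_cost Total projected cost.
#' @return Percentage (0--100 when `savings <= total_cost`).
#' @examples
#' reduction_percent(75, 100)
#' @export
reduction_percent <- function(savings, total_cost) {
  stopifnot(total_cost > 0, savings >= 0)
  100 * savings / total_cost
}

new_cost_summary <- function(scenario, currency, total_cost, ci_low, ci_high,
                             unit_cost, discount_rate, per_draw_cost,
                             benchmark_rate = NULL, savings = NULL,
                             savings_ci_low = NULL, savings_ci_high = NULL,
                             reduction_pct = NULL, per_draw_savings = NULL) {
  structure(
    list(scenario = scenario, currency = currency,
         total_cost = total_cost, ci_low = ci_low, ci_high = ci_high,
         unit_cost = unit_cost, discount_rate = discount_rate,
         per_draw_cost = per_draw_cost,
         benchmark_rate = benchmark_rate, savings = savings,
         savings_ci_low = savings_ci_low, savings_ci_high = savings_ci_high,
         reduction_pct = reduction_pct, per_draw_savings = per_draw_savings),
    class = "cost_summary"
  )
}

#' @describeIn total_cost Report rows
#'   (`scenario, measure, currency, value, ci_low, ci_high`).
#' @param x A `cost_summary`.
#' @param ... Unused.
#' @export
tidy.cost_summary <- function(x, ...) {
  rows <- tibble(scenario = x$scenario, measure = "total_cost",
                 currency = x$currency, value = x$total_cost,
                 ci_low = x$ci_low, ci_high = x$ci_high)
  if (!is.null(x$savings)) {
    rows <- dplyr::bind_rows(
      rows,
      tibble(scenario = x$scenario, measure = "benchmark_savings",
             currency = x$currency, value = x$savings,
             ci_low = x$savings_ci_low, ci_high = x$savings_ci_high),
      tibble(scenario = x$scenario, measure = "reduction_pct",
             currency = "percent", value = x$reduction_pct,
             ci_low = NA_real_, ci_high = NA_real_))
  }
  rows
}

#' @export
print.cost_summary <- function(x, ...) {
  cat(sprintf("<cost_summary '%s'> total %s %s (95%% CI %s-%s)\n",
              x$scenario, x$currency,
              format(round_half_up(x$total_cost), big.mark = ","),
              format(round_half_up(x$ci_low), big.mark = ","),
              format(round_half_up(x$ci_high), big.mark = ",")))
  if (!is.null(x$savings)) {
    cat(sprintf("  savings below %.0f/100k: %s %s (%.1f%% reduction)\n",
                x$benchmark_rate, x$currency,
                format(round_half_up(x$savings), big.mark = ","),
                x$reduction_pct))
  }
  invisible(x)
}
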