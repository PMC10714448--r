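# Bootstrap of the joint (y0, b0, b1) distribution of the final stable
# trend segment.  The default is a parametric Poisson bootstrap: counts are
# redrawn from the fitted segment means and the full change-point model is
# refitted each iteration, so the change-point location varies jointly with
# the final segment's coefficients.  Case resampling of years is available
# as an alternative.

#' Bootstrap the joint distribution of the final trend segment
#'
#' Each iteration resamples the series, refits the full change-point model
#' with the same settings (the number and placement of change points are
#' re-estimated every time), and records the final segment's
#' `(y0, beta0, beta1)`: the segment start year, its log per-person rate
#' intercept and per-year slope.  Iterations whose refit fails or whose
#' final segment is degenerate are redrawn and counted; more than
#' `max_failure_frac` failures aborts with a diagnostic.  Per-iteration RNG
#' substreams are derived from `seed` by a counter, so the draw for
#' iteration `i` does not depend on how earlier iterations were evaluated.
#'
#' @param series The data frame the fit was produced from.
#' @param fit The [fit_segmented_poisson()] fit of `series` (same
#'   exclusions).
#' @param n_iterations Number of bootstrap draws (conventionally 1000).
#' @param seed Integer root seed.
#' @param type `"parametric"` (Poisson redraw from fitted means, the
#'   default) or `"case"` (resample included years with replacement,
#'   refitting with multiplicity weights).
#' @param max_failure_frac Abort threshold for the failed-iteration
#'   fraction.
#' @return A `bootstrap_draws` object; `tidy()` returns the draw table
#'   `iteration, y0, beta0, beta1`.
#' @examples
#' preset <- synthetic_preset(seed = 1)
#' fit <- fit_segmented_poisson(preset$series, excluded_years = 2020,
#'                              max_changepoints = 1)
#' draws <- bootstrap_fit(preset$series, fit, n_iterations = 20, seed = 7)
#' tidy(draws)
#' @export
bootstrap_fit <- function(series, fit, n_iterations = 1000, seed = 1L,
                          type = c("parametric", "case"),
                          max_failure_frac = 0.1) {
  type <- match.arg(type)
  stopifnot(inherits(fit, "changepoint_fit"), n_iterations >= 1)
  series <- annual_series(series)
  if (!identical(series$year, fit$series$year) ||
      !identical(series$count, fit$series$count)) {
    abort("`fit` was not produced from `series` (years or counts differ).")
  }

  years <- series$year
  pop <- series$population
  included <- !(years %in% fit$excluded_years)
  mu <- fitted_means(fit)$mean
  n_inc <- sum(included)
  inc_idx <- which(included)
  max_cp <- fit$settings$max_changepoints
  min_seg <- fit$settings$min_segment_len

  y0 <- beta0 <- beta1 <- numeric(n_iterations)
  n_failures <- 0L
  counter <- 0L
  max_failures <- floor(max_failure_frac * n_iterations)

  for (i in seq_len(n_iterations)) {
    repeat {
      counter <- counter + 1L
      res <- withr_seed(derive_seed(seed, counter), {
        if (type == "parametric") {
          counts_i <- series$count
          counts_i[included] <- rpois(n_inc, mu[included])
          w <- NULL
        } else {
          counts_i <- series$count
          picked <- sample(inc_idx, n_inc, replace = TRUE)
          w <- tabulate(picked, nbins = length(years))
        }
        tryCatch(
          fit_segmented_core(years, counts_i, pop, included,
                             max_cp, min_seg, w = w),
          error = function(e) NULL)
      })
      final <- if (!is.null(res)) res$segments[[length(res$segments)]]
      if (!is.null(final) && !final$degenerate) break
      n_failures <- n_failures + 1L
      if (n_failures > max_failures) {
        abort(sprintf(
          "Bootstrap aborted: %d failed iterations (> %.0f%% of %d).",
          n_failures, 100 * max_failure_frac, n_iterations))
      }
    }
    y0[i] <- final$start_year
    beta0[i] <- final$intercept
    beta1[i] <- final$slope
  }

  structure(
    list(draws = tibble(iteration = seq_len(n_iterations),
                        y0 = y0, beta0 = beta0, beta1 = beta1),
         n_iterations = as.integer(n_iterations), seed = as.integer(seed),
         type = type, n_failures = n_failures,
         settings = fit$settings, excluded_years = fit$excluded_years),
    class = "bootstrap_draws"
  )
}

#' @describeIn bootstrap_fit The draw table (`iteration, y0, beta0, beta1`).
#' @param x A `bootstrap_draws` object.
#' @param ... Unused.
#' @export
tidy.bootstrap_draws <- function(x, ...) x$draws

#' @export
print.bootstrap_draws <- function(x, ...) {
  cat(sprintf("<bootstrap_draws> %d %s iterations (seed %d, %d failures)\n",
              x$n_iterations, x$type, x$seed, x$n_failures))
  q <- quantile(x$draws$beta1, c(0.025, 0.5, 0.975))
  cat(sprintf("  beta1 median %+.4f (95%%: %+.4f to %+.4f); y0 mode %d\n",
              q[2], q[1], q[3],
              as.integer(names(which.max(table(x$draws$y0))))))
  invisible(x)
}

#' Annual-percent-change trend estimate with bootstrap credible interval
#'
#' Combines the point fit's final-segment slope with percentile bounds from
#' the bootstrap draws: the reported trend is `100 * (exp(b1) - 1)` with the
#' 2.5th/97.5th percentiles of the same transform of the drawn `beta1`.
#'
#' @param fit A [fit_segmented_poisson()] fit.
#' @param draws Matching [bootstrap_fit()] draws.
#' @param level Credible level (default 0.95, percentile bootstrap).
#' @return One-row tibble: `segment_index`, `annual_percent_change`,
#'   `ci_low`, `ci_high`.
#' @export
trend_estimate <- function(fit, draws, level = 0.95) {
  stopifnot(inherits(draws, "bootstrap_draws"))
  apc_draws <- 100 * (exp(draws$draws$beta1) - 1)
  alpha <- (1 - level) / 2
  q <- unname(quantile(apc_draws, c(alpha, 1 - alpha)))
  tibble(segment_index = nrow(fit$segments),
         annual_percent_change = annual_percent_change(fit),
         ci_low = q[1], ci_high = q[2])
}
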