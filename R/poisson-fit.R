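# Per-segment Poisson log-linear fit with a log-population offset:
#   count_y ~ Poisson(P_y * exp(b0 + b1 * (y - anchor)))
# Two-parameter Newton iteration with analytic gradient/Hessian and
# step-halving; the log-likelihood is concave in (b0, b1), so the iteration
# is globally convergent.  This fitter sits in the hot path of the
# change-point search and the bootstrap (~1e5 calls), hence plain vectors.

# t: year - anchor; w: per-observation multiplicity weights.
# Returns list(intercept, slope, loglik, degenerate, n_iter).
fit_poisson_segment <- function(t, counts, pop, w = NULL) {
  if (is.null(w)) w <- rep.int(1, length(t))
  wy <- sum(w * counts)
  if (wy == 0) {
    # All-zero segment: likelihood maximised in the limit rate -> 0.
    return(list(intercept = -Inf, slope = 0,
                loglik = 0, degenerate = TRUE, n_iter = 0L))
  }
  b0 <- log(wy / sum(w * pop))
  b1 <- 0
  logp <- log(pop)
  loglik_at <- function(b0, b1) {
    eta <- b0 + b1 * t
    sum(w * (counts * (logp + eta) - pop * exp(eta) - lfactorial(counts)))
  }
  ll <- loglik_at(b0, b1)
  tol <- max(1e-10, 1e-12 * wy)
  converged <- FALSE
  iter <- 0L
  for (iter in seq_len(100L)) {
    mu <- w * pop * exp(b0 + b1 * t)
    r <- w * counts - mu
    g1 <- sum(r)
    g2 <- sum(r * t)
    if (max(abs(g1), abs(g2)) < tol) { converged <- TRUE; break }
    h11 <- sum(mu)
    h12 <- sum(mu * t)
    h22 <- sum(mu * t * t)
    det <- h11 * h22 - h12 * h12
    if (!is.finite(det) || det <= 0) {
      abort("Singular Hessian in Poisson segment fit (time values collinear?).")
    }
    d0 <- (h22 * g1 - h12 * g2) / det
    d1 <- (h11 * g2 - h12 * g1) / det
    # Step-halve until the likelihood does not decrease.
    step <- 1
    repeat {
      ll_new <- loglik_at(b0 + step * d0, b1 + step * d1)
      if (is.finite(ll_new) && ll_new >= ll - 1e-12 * abs(ll)) break
      step <- step / 2
      if (step < 1e-12) break
    }
    b0 <- b0 + step * d0
    b1 <- b1 + step * d1
    ll <- ll_new
  }
  if (!converged) {
    abort("Poisson segment fit did not converge within 100 iterations.")
  }
  list(intercept = b0, slope = b1, loglik = ll,
       degenerate = FALSE, n_iter = iter)
}

#' Poisson log-linear fit over one span of an annual series
#'
#' Maximises the Poisson log-likelihood of
#' `count_y ~ Poisson(P_y * exp(b0 + b1 * (y - span_start)))` over the
#' included years of `year_span`, i.e. a single trend segment with the log
#' population as offset and time anchored at the span start.  An all-zero
#' span is degenerate: the rate estimate is 0, reported as `intercept =
#' -Inf`, `slope = 0`, `loglik = 0`.
#'
#' @param series Data frame accepted by [annual_series()].
#' @param year_span Length-2 inclusive year range `c(first, last)`.
#' @param excluded_years Years inside the span to drop from the likelihood
#'   (the calendar time index is kept, so exclusion does not renumber years).
#' @return One-row tibble: `loglik`, `intercept` (log per-person rate at the
#'   span start), `slope` (per-year change in log rate), `degenerate`,
#'   `n_included`.
#' @examples
#' s <- annual_series(data.frame(year = 2000:2004, count = 50,
#'                               population = 1e6))
#' segment_loglik(s, c(2000, 2004))  # slope 0, intercept log(5e-5)
#' @export
segment_loglik <- function(series, year_span, excluded_years = integer()) {
  series <- annual_series(series)
  stopifnot(length(year_span) == 2, year_span[1] <= year_span[2])
  in_span <- series$year >= year_span[1] & series$year <= year_span[2]
  keep <- in_span & !(series$year %in% excluded_years)
  if (sum(keep) < 2) {
    abort("Span must contain at least 2 included years.")
  }
  f <- fit_poisson_segment(series$year[keep] - year_span[1],
                           series$count[keep], series$population[keep])
  tibble(loglik = f$loglik, intercept = f$intercept, slope = f$slope,
         degenerate = f$degenerate, n_included = sum(keep))
}
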