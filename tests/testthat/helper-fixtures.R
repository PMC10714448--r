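# Shared fixtures and independent oracles.

# Constant-population series with explicit counts.
make_series <- function(years, counts, population = 1e6) {
  annual_series(tibble::tibble(year = years, count = counts,
                               population = population))
}

# Independent per-segment fit via stats::glm (offset-Poisson), anchored at
# the span's first year.  Used as the cross-check oracle for the package's
# Newton fitter.
glm_segment <- function(series, from, to, excluded_years = integer()) {
  d <- series[series$year >= from & series$year <= to &
                !(series$year %in% excluded_years), ]
  if (sum(d$count) == 0) {
    return(list(loglik = 0, intercept = -Inf, slope = 0))
  }
  g <- stats::glm(count ~ I(year - from), family = stats::poisson,
                  offset = log(population), data = d,
                  control = stats::glm.control(epsilon = 1e-12, maxit = 100))
  list(loglik = as.numeric(stats::logLik(g)),
       intercept = unname(stats::coef(g)[1]),
       slope = unname(stats::coef(g)[2]))
}

# Brute-force change-point search: enumerate every admissible placement of
# k change years with glm segment fits, entirely independent of the
# production search.  Returns the best placement and log-likelihood per k
# and the BIC-selected model.
brute_force_segmented <- function(series, excluded_years = integer(),
                                  max_changepoints = 2, min_segment_len = 3) {
  years <- series$year
  n <- length(years)
  included <- !(years %in% excluded_years)
  n_inc <- sum(included)
  seg_ll <- function(i, j) glm_segment(series, years[i], years[j],
                                       excluded_years)$loglik
  best <- NULL
  for (k in 0:max_changepoints) {
    placements <- if (k == 0) list(integer()) else {
      m <- utils::combn(2:n, k)
      lapply(seq_len(ncol(m)), function(c) m[, c])
    }
    best_k <- NULL
    for (b in placements) {
      starts <- c(1L, b)
      ends <- c(b - 1L, n)
      sizes <- vapply(seq_along(starts), function(s) {
        sum(included[starts[s]:ends[s]])
      }, integer(1))
      if (any(sizes < min_segment_len)) next
      ll <- sum(vapply(seq_along(starts), function(s) {
        seg_ll(starts[s], ends[s])
      }, numeric(1)))
      if (is.null(best_k) || ll > best_k$loglik) {
        best_k <- list(k = k, change_years = years[b], loglik = ll)
      }
    }
    if (is.null(best_k)) next
    best_k$bic <- -2 * best_k$loglik + (2 * (k + 1) + k) * log(n_inc)
    if (is.null(best) || best_k$bic < best$bic) best <- best_k
  }
  best
}

# A clean two-segment test series with large counts (tight estimates).
two_segment_series <- function(seed = 1, change_year = 2003,
                               pre_slope = -0.05, post_slope = 0,
                               base_rate = 3000 / 4e6,
                               years = 1994:2019, population = 4e6) {
  pre_years <- change_year - min(years)
  tr <- piecewise_rates(
    min(years), max(years), change_years = change_year,
    intercepts = c(log(base_rate) - pre_slope * pre_years, log(base_rate)),
    slopes = c(pre_slope, post_slope))
  pop <- tibble::tibble(year = years, population = population)
  generate_counts(tr, pop, seed = seed)
}
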