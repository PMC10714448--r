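# Segmented Poisson trend fitting with unknown integer-year change points.
# The change-year placement for each candidate k is found by exhaustive
# enumeration over admissible placements (exact at annual-series sizes),
# with per-span segment fits memoised; k is then selected by BIC, ties
# broken toward fewer change points.

# Internal search over plain vectors (hot path: called per bootstrap
# iteration).  `included` marks years that enter the likelihood; `w` are
# per-year multiplicity weights (case bootstrap), default 1.
fit_segmented_core <- function(years, counts, pop, included,
                               max_changepoints, min_segment_len, w = NULL) {
  n <- length(years)
  if (is.null(w)) w <- rep.int(1, n)
  included <- included & w > 0
  inc_cum <- cumsum(included)
  n_inc <- function(i, j) inc_cum[j] - if (i > 1) inc_cum[i - 1] else 0
  n_inc_total <- inc_cum[n]
  if (n_inc_total < 2) abort("Need at least 2 included years to fit.")
  n_obs <- sum(w[included])  # BIC sample size (= n_inc_total unless weighted)

  cache <- vector("list", n * n)
  seg_fit <- function(i, j) {
    key <- (i - 1L) * n + j
    f <- cache[[key]]
    if (is.null(f)) {
      keep <- included
      if (i > 1) keep[seq_len(i - 1)] <- FALSE
      if (j < n) keep[(j + 1):n] <- FALSE
      f <- fit_poisson_segment(years[keep] - years[i], counts[keep],
                               pop[keep], w[keep])
      f$i <- i
      f$j <- j
      cache[[key]] <<- f
    }
    f
  }

  placement_loglik <- function(bounds) {
    # bounds: indices of first years of segments 2..k+1 (possibly empty)
    starts <- c(1L, bounds)
    ends <- c(bounds - 1L, n)
    ll <- 0
    for (s in seq_along(starts)) {
      ll <- ll + seg_fit(starts[s], ends[s])$loglik
    }
    ll
  }

  by_k <- list()
  short_series <- FALSE
  kmax <- max(0L, as.integer(max_changepoints))
  any_k_ge1 <- FALSE
  for (k in 0:kmax) {
    if (k == 0) {
      best_ll <- placement_loglik(integer())
      best_bounds <- integer()
    } else {
      cand <- 2:n
      if (length(cand) < k) next
      combos <- utils::combn(cand, k)
      best_ll <- -Inf
      best_bounds <- NULL
      for (ci in seq_len(ncol(combos))) {
        b <- combos[, ci]
        starts <- c(1L, b)
        ends <- c(b - 1L, n)
        ok <- TRUE
        for (s in seq_along(starts)) {
          if (n_inc(starts[s], ends[s]) < min_segment_len) { ok <- FALSE; break }
        }
        if (!ok) next
        ll <- placement_loglik(b)
        if (ll > best_ll) {
          best_ll <- ll
          best_bounds <- b
        }
      }
      if (is.null(best_bounds)) next
      any_k_ge1 <- TRUE
    }
    n_params <- 2 * (k + 1) + k
    by_k[[length(by_k) + 1]] <- list(
      k = k, bounds = best_bounds, loglik = best_ll,
      n_params = n_params, bic = -2 * best_ll + n_params * log(n_obs))
  }
  if (kmax >= 1 && !any_k_ge1) short_series <- TRUE

  best <- by_k[[1]]
  for (m in by_k[-1]) if (m$bic < best$bic) best <- m

  bounds <- best$bounds
  starts <- c(1L, bounds)
  ends <- c(bounds - 1L, n)
  segments <- lapply(seq_along(starts), function(s) {
    f <- seg_fit(starts[s], ends[s])
    list(segment = s, start_year = years[starts[s]], end_year = years[ends[s]],
         n_included = n_inc(starts[s], ends[s]),
         intercept = f$intercept, slope = f$slope, loglik = f$loglik,
         degenerate = f$degenerate)
  })
  list(k = best$k, change_years = years[bounds], segments = segments,
       loglik = best$loglik, n_params = best$n_params, bic = best$bic,
       n_obs = n_obs, by_k = by_k, short_series = short_series)
}

#' Fit a segmented log-linear Poisson trend with unknown change points
#'
#' Models annual episode counts as Poisson with per-person rate
#' `exp(b0_s + b1_s * (year - start_s))` within each trend segment `s`, the
#' log population entering as offset.  For each candidate number of change
#' points `k <= max_changepoints`, the placement of integer change years
#' maximising the total log-likelihood is found by exhaustive enumeration;
#' the returned `k` minimises `BIC = -2*loglik + (2(k+1)+k)*log(n)`, with
#' ties broken toward fewer change points.  Years in `excluded_years` (for
#' instance a pandemic-disrupted year) are dropped from the likelihood and
#' the search while the calendar time index is preserved.
#'
#' @param series Data frame accepted by [annual_series()].
#' @param excluded_years Years to exclude from fitting.
#' @param max_changepoints Largest number of change points considered.
#' @param min_segment_len Minimum included years per segment.
#' @return A `changepoint_fit` object; see [tidy.changepoint_fit()] and
#'   [glance.changepoint_fit()] for tabular views.  Its `segments` element
#'   holds each segment's start year, intercept (log per-person rate at the
#'   segment start) and per-year slope; the final segment carries the
#'   `(y0, b0, b1)` triple used for projection.
#' @examples
#' preset <- synthetic_preset(seed = 1)
#' fit <- fit_segmented_poisson(preset$series, excluded_years = 2020)
#' tidy(fit)
#' @export
fit_segmented_poisson <- function(series, excluded_years = integer(),
                                  max_changepoints = 3, min_segment_len = 3) {
  series <- annual_series(series)
  if (max_changepoints < 0) abort("`max_changepoints` must be >= 0.")
  if (min_segment_len < 2) abort("`min_segment_len` must be >= 2.")
  included <- !(series$year %in% excluded_years)
  core <- fit_segmented_core(series$year, series$count, series$population,
                             included, max_changepoints, min_segment_len)
  if (core$short_series) {
    warn("Series too short for any change point; returning the k = 0 fit.")
  }
  new_changepoint_fit(core, series, excluded_years,
                      list(max_changepoints = max_changepoints,
                           min_segment_len = min_segment_len))
}

new_changepoint_fit <- function(core, series, excluded_years, settings) {
  segments <- dplyr::bind_rows(lapply(core$segments, as_tibble))
  by_k <- dplyr::bind_rows(lapply(core$by_k, function(m) {
    tibble(k = m$k, loglik = m$loglik, n_params = m$n_params, bic = m$bic,
           change_years = paste(series$year[m$bounds], collapse = ";"))
  }))
  structure(
    list(change_years = as.integer(core$change_years),
         segments = segments,
         loglik = core$loglik, n_params = core$n_params, bic = core$bic,
         n_included = core$n_obs,
         excluded_years = as.integer(excluded_years),
         bic_by_k = by_k, short_series = core$short_series,
         series = series, settings = settings),
    class = "changepoint_fit"
  )
}

#' Annual percent change implied by a fitted segment slope
#'
#' Converts the per-year log-rate slope `b1` of a segment into the annual
#' percent change `100 * (exp(b1) - 1)`.
#'
#' @param fit A `changepoint_fit`.
#' @param segment_index Which segment (default: the final, projectable one).
#' @return Percent change per year (scalar).
#' @examples
#' preset <- synthetic_preset(seed = 1)
#' fit <- fit_segmented_poisson(preset$series, excluded_years = 2020)
#' annual_percent_change(fit)
#' @export
annual_percent_change <- function(fit, segment_index = nrow(fit$segments)) {
  stopifnot(inherits(fit, "changepoint_fit"))
  if (segment_index < 1 || segment_index > nrow(fit$segments)) {
    abort("Invalid segment index.")
  }
  seg <- fit$segments[segment_index, ]
  if (seg$degenerate) {
    abort("Segment is degenerate (all counts zero); trend undefined.")
  }
  100 * (exp(seg$slope) - 1)
}

# Fitted Poisson means per year (0 for degenerate segments).
fitted_means <- function(fit) {
  stopifnot(inherits(fit, "changepoint_fit"))
  years <- fit$series$year
  starts <- fit$segments$start_year
  seg <- findInterval(years, starts)
  b0 <- fit$segments$intercept[seg]
  b1 <- fit$segments$slope[seg]
  mu <- fit$series$population * exp(b0 + b1 * (years - starts[seg]))
  mu[!is.finite(mu)] <- 0  # -Inf intercept: degenerate zero-rate segment
  tibble(year = years, mean = mu,
         included = !(years %in% fit$excluded_years))
}

#' @describeIn fit_segmented_poisson Per-segment estimates: start/end year,
#'   intercept, slope, annual percent change, log-likelihood.
#' @param x,object A `changepoint_fit`.
#' @param ... Unused.
#' @export
tidy.changepoint_fit <- function(x, ...) {
  out <- x$segments
  out$apc <- ifelse(out$degenerate, NA_real_, 100 * (exp(out$slope) - 1))
  out
}

#' @describeIn fit_segmented_poisson One-row model summary: number of change
#'   points, log-likelihood, parameter count, BIC, included years.
#' @export
glance.changepoint_fit <- function(x, ...) {
  tibble(n_changepoints = length(x$change_years),
         change_years = paste(x$change_years, collapse = ";"),
         loglik = x$loglik, n_params = x$n_params, bic = x$bic,
         n_included = x$n_included,
         excluded_years = paste(x$excluded_years, collapse = ";"))
}

#' @export
print.changepoint_fit <- function(x, ...) {
  k <- length(x$change_years)
  cat(sprintf("<changepoint_fit> %d change point%s", k, if (k == 1) "" else "s"))
  if (k > 0) cat(" at ", paste(x$change_years, collapse = ", "), sep = "")
  cat(sprintf("\n  years %d-%d (%d included", min(x$series$year),
              max(x$series$year), x$n_included))
  if (length(x$excluded_years)) {
    cat("; excluded ", paste(x$excluded_years, collapse = ", "), sep = "")
  }
  cat(sprintf(")\n  loglik %.2f, BIC %.2f\n", x$loglik, x$bic))
  seg <- tidy(x)
  for (i in seq_len(nrow(seg))) {
    cat(sprintf("  segment %d [%d-%d]: slope %+.4f (APC %+.2f%%/yr)\n",
                i, seg$start_year[i], seg$end_year[i], seg$slope[i],
                seg$apc[i]))
  }
  invisible(x)
}

#' @describeIn fit_segmented_poisson Observed rates per 100,000 (excluded
#'   years hollow) with the fitted per-segment trend and change years.
#' @export
autoplot.changepoint_fit <- function(object, ...) {
  obs <- object$series
  obs$included <- !(obs$year %in% object$excluded_years)
  fit_line <- fitted_means(object)
  fit_line$rate <- fit_line$mean / object$series$population * 1e5
  starts <- object$segments$start_year
  fit_line$segment <- factor(findInterval(fit_line$year, starts))
  p <- ggplot2::ggplot(obs, ggplot2::aes(x = .data$year)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$rate_per_100k,
                                     shape = .data$included)) +
    ggplot2::scale_shape_manual(values = c(`TRUE` = 16, `FALSE` = 1),
                                guide = "none") +
    ggplot2::geom_line(data = fit_line,
                       ggplot2::aes(y = .data$rate, group = .data$segment),
                       colour = "steelblue") +
    ggplot2::labs(x = "Year", y = "Episodes per 100,000",
                  title = "Segmented Poisson trend fit")
  if (length(object$change_years)) {
    p <- p + ggplot2::geom_vline(xintercept = object$change_years,
                                 linetype = "dashed", colour = "grey50")
  }
  p
}
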