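# Segmented Poisson fitting: per-segment likelihood, exhaustive search,
# BIC selection, annual percent change.

test_that("segment fits hit closed-form stationary points", {
  # constant counts: slope 0, intercept log(c/P) exactly
  s <- make_series(2000:2009, counts = rep(50, 10), population = 1e6)
  f <- segment_loglik(s, c(2000, 2009))
  expect_equal(f$slope, 0, tolerance = 1e-9)
  expect_equal(f$intercept, log(50 / 1e6), tolerance = 1e-9)

  # two observations, two parameters: exact interpolation
  s2 <- make_series(2000:2001, counts = c(100, 110), population = 1e6)
  f2 <- segment_loglik(s2, c(2000, 2001))
  expect_equal(f2$slope, log(110 / 100), tolerance = 1e-9)
  expect_equal(f2$intercept, log(100 / 1e6), tolerance = 1e-9)

  # counts generated as P * r * g^t recover log(g)
  years <- 2000:2019
  counts <- round(1e6 * 8e-4 * 1.017^(years - 2000))
  f3 <- segment_loglik(make_series(years, counts), c(2000, 2019))
  expect_equal(f3$slope, log(1.017), tolerance = 1e-3)

  # all-zero span is degenerate with zero log-likelihood
  f4 <- segment_loglik(make_series(2000:2005, rep(0, 6)), c(2000, 2005))
  expect_true(f4$degenerate)
  expect_equal(f4$intercept, -Inf)
  expect_equal(f4$loglik, 0)
})

test_that("the Newton fitter agrees with glm on irregular data", {
  set.seed(99)
  for (rep in 1:5) {
    counts <- rpois(12, exp(log(5e-4) + 0.03 * (0:11)) * 2e6)
    s <- make_series(2001:2012, counts, population = 2e6)
    mine <- segment_loglik(s, c(2001, 2012))
    oracle <- glm_segment(s, 2001, 2012)
    expect_equal(mine$intercept, oracle$intercept, tolerance = 1e-7)
    expect_equal(mine$slope, oracle$slope, tolerance = 1e-7)
    expect_equal(mine$loglik, oracle$loglik, tolerance = 1e-7)
  }
})

test_that("annual percent change is the exact inverse log transform", {
  s <- two_segment_series(seed = 2)
  fit <- fit_segmented_poisson(s, max_changepoints = 1)
  seg <- fit$segments
  expect_equal(annual_percent_change(fit, 1),
               100 * (exp(seg$slope[1]) - 1))
  # round trip over a grid of percent changes
  for (p in seq(-50, 50, by = 10)) {
    expect_equal(100 * (exp(log(1 + p / 100)) - 1), p, tolerance = 1e-10)
  }
  # frozen spot values (oracle: direct evaluation of 100*(e^b1 - 1))
  expect_equal(100 * (exp(log(1.017)) - 1), 1.7, tolerance = 1e-10)
  expect_equal(100 * (exp(-0.0346) - 1), -3.4008255, tolerance = 1e-6)

  # degenerate segment has no defined trend
  zfit <- fit_segmented_poisson(make_series(2000:2009, rep(0, 10)),
                                max_changepoints = 0)
  expect_error(annual_percent_change(zfit), "degenerate")
})

test_that("production search equals brute-force enumeration on small series", {
  set.seed(2024)
  for (rep in 1:10) {
    n <- sample(10:14, 1)
    years <- 2000:(2000 + n - 1)
    # random piecewise structure with 0-2 true changes
    k_true <- sample(0:2, 1)
    cut <- sort(sample(years[c(-1, -2, -n + 1, -n)], k_true))
    starts <- c(years[1], cut)
    seg <- findInterval(years, starts)
    slopes <- stats::runif(k_true + 1, -0.1, 0.1)
    rates <- exp(log(stats::runif(1, 2e-4, 1e-3)) +
                   slopes[seg] * (years - starts[seg]))
    counts <- rpois(n, 5e5 * rates)
    s <- make_series(years, counts, population = 5e5)

    got <- fit_segmented_poisson(s, max_changepoints = 2,
                                 min_segment_len = 3)
    want <- brute_force_segmented(s, max_changepoints = 2,
                                  min_segment_len = 3)
    expect_equal(length(got$change_years), want$k)
    expect_equal(got$change_years, as.integer(want$change_years))
    expect_equal(got$loglik, want$loglik, tolerance = 1e-6)
    expect_equal(got$bic, want$bic, tolerance = 1e-6)
  }
})

test_that("optimal log-likelihood is non-decreasing in k", {
  s <- two_segment_series(seed = 4)
  fit <- fit_segmented_poisson(s, max_changepoints = 3)
  lls <- fit$bic_by_k$loglik[order(fit$bic_by_k$k)]
  expect_true(all(diff(lls) >= -1e-8))
})

test_that("doubling the population shifts intercepts by -log 2 and keeps slopes", {
  s <- two_segment_series(seed = 6)
  fit1 <- fit_segmented_poisson(s, max_changepoints = 2)
  s2 <- s
  s2$population <- s2$population * 2
  fit2 <- fit_segmented_poisson(annual_series(s2), max_changepoints = 2)
  expect_identical(fit2$change_years, fit1$change_years)
  expect_equal(fit2$segments$slope, fit1$segments$slope, tolerance = 1e-8)
  expect_equal(fit2$segments$intercept, fit1$segments$intercept - log(2),
               tolerance = 1e-8)
})

test_that("excluding the shocked year reproduces the unshocked fit exactly", {
  s <- two_segment_series(seed = 8, years = 1994:2020)
  shocked <- inject_shock(s, 2020, 0.5, seed = 1)
  f_orig <- fit_segmented_poisson(s, excluded_years = 2020,
                                  max_changepoints = 2)
  f_shock <- fit_segmented_poisson(shocked, excluded_years = 2020,
                                   max_changepoints = 2)
  # only the excluded year differs, so the likelihoods are identical
  expect_identical(f_shock$change_years, f_orig$change_years)
  expect_equal(f_shock$segments$slope, f_orig$segments$slope,
               tolerance = 1e-12)
  expect_equal(f_shock$loglik, f_orig$loglik, tolerance = 1e-10)
})

test_that("short series fall back to k = 0 with a warning", {
  s <- make_series(2000:2004, counts = c(40, 42, 39, 41, 40))
  expect_warning(fit <- fit_segmented_poisson(s, max_changepoints = 2,
                                              min_segment_len = 3),
                 "too short")
  expect_length(fit$change_years, 0)
  expect_true(fit$short_series)
})

test_that("tidy/glance expose the fitted segments and model score", {
  s <- two_segment_series(seed = 10)
  fit <- fit_segmented_poisson(s, excluded_years = 2019,
                               max_changepoints = 2)
  td <- tidy(fit)
  expect_true(all(c("segment", "start_year", "intercept", "slope", "apc")
                  %in% names(td)))
  expect_equal(nrow(td), length(fit$change_years) + 1)
  gl <- glance(fit)
  expect_equal(gl$bic, -2 * gl$loglik + gl$n_params * log(gl$n_included))
  expect_equal(gl$excluded_years, "2019")
  expect_s3_class(autoplot(fit), "ggplot")
})
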