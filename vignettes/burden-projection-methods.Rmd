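---
title: "Methods: change-point trends, bootstrap projection and costing of acute-care burden"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: change-point trends, bootstrap projection and costing of acute-care burden}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(burdenproj)
```

`burdenproj` estimates how the population-level burden of an acute-care
outcome (hospital admissions, emergency-department attendances, deaths) has
evolved over a few decades of annual data, and projects it forward under
demographic scenarios, with costs attached. This vignette is the package's
own account of the statistical machinery: the model, the choices we made
where several defensible options existed, and what the synthetic-data tests
do and do not establish.

## The trend model

The data are an annual series: calendar years $y$, episode counts $c_y$,
and resident population $P_y$. We model counts as Poisson with a
piecewise log-linear per-person rate,

$$c_y \sim \mathrm{Poisson}\!\left(P_y\, e^{\beta_{0,s} + \beta_{1,s}(y - y_{0,s})}\right),$$

where $s$ indexes trend segments separated by integer-year change points,
$y_{0,s}$ is the first year of segment $s$, and the log population enters
as an offset so that $\beta$ describes rates per person, not raw counts.
Rates are parameterised per person internally; the conventional "per
100,000" scale appears only at I/O and in plots, which keeps the Poisson
mean formulation exact. The slope converts to an annual percent change
(APC) as $100(e^{\beta_1} - 1)$: a slope of $\log 1.017$ is a 1.7% yearly
increase.

Assumptions worth stating: counts are conditionally independent across
years given the trend (no autocorrelation), the variance equals the mean
(no overdispersion — see Limitations), and population denominators are
treated as known.

### Fitting a single segment

Each segment is a two-parameter Poisson regression, fitted by Newton
iteration on the analytic gradient and Hessian with step-halving. The
log-likelihood of a log-linear Poisson model is concave, so the iteration
is globally convergent; we stop when the gradient norm falls below
$\max(10^{-10},\,10^{-12}\sum_y c_y)$ (the relative guard keeps
machine-precision noise from stalling convergence on large-count series)
and error out after 100 iterations. A segment whose included counts are
all zero is degenerate: its rate estimate is 0, reported as intercept
$-\infty$ with zero log-likelihood contribution, and no APC is defined for
it. The fitter is cross-checked against `stats::glm` in the test suite.

### Change-point search and model selection

For each candidate number of change points $k$ up to `max_changepoints`
(default 3), every admissible placement of integer change years is
enumerated exhaustively — at 25–30 annual observations this is a few
thousand placements, each scored by summing memoised per-span segment
fits, so the optimum is exact rather than heuristic. A placement is
admissible when every segment contains at least `min_segment_len` included
years (default 3; shorter segments make slope estimates meaningless). The
number of change points is then chosen by
$\mathrm{BIC} = -2\ell + [2(k+1)+k]\log n$, counting each change-point
location as a parameter, with ties broken toward fewer change points. A
series too short for any change point returns the $k=0$ fit with a
warning.

Years can be excluded from fitting — the motivating use is a
pandemic-disrupted year whose utilisation collapse is transient and should
not bend the long-run trend. Excluded years are dropped from the
likelihood, the search, and bootstrap resampling, but the calendar time
index is untouched, so exclusion never renumbers years. Because only the
excluded year's count differs, fitting a shocked series with the shock
year excluded is *identical* to fitting the unshocked series with that
year excluded; the suite asserts this exactly.

### Uncertainty: parametric bootstrap of $(y_0, \beta_0, \beta_1)$

Projection uses the final stable segment: its start year $y_0$ (the last
change point), intercept $\beta_0$ and slope $\beta_1$. All three are
uncertain, and $y_0$ is the awkward one — it is an integer-valued estimate
whose variability shifts the anchor of the whole extrapolation. We
therefore bootstrap the *joint* distribution: each of `n_iterations`
(default 1000) iterations redraws every included count from
$\mathrm{Poisson}(\hat\mu_y)$ at the fitted means, refits the full
change-point model (the number *and* placement of change points are
re-estimated each time), and records the refitted final segment's
$(y_0, \beta_0, \beta_1)$. Case resampling of years is available as an
option (`type = "case"`, implemented via per-year multiplicity weights),
but the parametric form is the default because it respects the annual
design and the Poisson mean–variance link. Intervals are percentile
(2.5th–97.5th) throughout; basic or BCa intervals were not implemented
because the quantities of interest (projected totals) are smooth monotone
transforms of the draws, where percentile intervals behave well.

Each iteration draws its RNG substream from the root seed and an iteration
counter, so results are reproducible and independent of evaluation order.
Failed refits are redrawn and counted; more than 10% failures aborts.

## Projection under demographic scenarios

Each draw projects forward as

$$N(y) = P_y \, e^{\beta_0 + \beta_1 (y - y_0)},$$

with the scenario's population trajectory supplying $P_y$. At $y = y_0$
the projection depends only on $\beta_0$ and the population (the suite
checks this anchor invariance), and it is exactly linear in $P_y$, so
scenario comparisons isolate the demographic assumption: the same draws
are reused across scenarios and only the population changes. Projected
rates reaching 1 per person trigger an error rather than a silently absurd
extrapolation.

Per-year summaries are medians with percentile bounds across draws; period
totals are computed *per draw* before taking percentiles (summing per-year
percentiles would misstate the interval because trajectories are
correlated across years). The point estimate is the median of draws, for
consistency with the percentile intervals. Episodes stay fractional
through every aggregation and are rounded half-up only in final reports.
The default horizon is 2023–2040 inclusive (18 years), configurable; the
anchoring year of the trend is always the fitted $y_0$, so the horizon
choice only selects which years are reported.

Scenario populations come from a one-line recurrence,
$P_{y+1} = P_y(1 + g) + m$, with natural growth $g$ (the fertility/
mortality balance as a per-year fraction) and annual net migration $m$.
This is deliberately not a cohort-component model: the analysis consumes
population trajectories, and for scenario comparison all that matters is a
family of plausible trajectories ordered by the migration assumption
(default $m \in \{0,\ 30000,\ 60000\}$ persons/year with shared $g$).
Populations are carried as reals internally and rounded half-up to whole
persons only on export, so no rounding drift compounds through the
recurrence.

## Costing

Two per-episode unit costs are constructed. The hospitalisation cost is
length of stay (default 2 days) times the daily ward cost (default 500 SGD
in 2013 prices) inflated to the 2022 reference year; the inflation step is
applied to the stay total with the factor at full precision, then rounded
to cents. The default factor is 1.11665: published figures derived from a
558.33 SGD inflated day-cost and a 1116.65 SGD two-day episode differ by
one cent, and 1.11665 is the value that makes the episode total exact
(the per-day figure then rounds to 558.33). A `rounding` flag
(`half_up`, the default, or `truncate`) exposes the convention instead of
hiding it. The ED cost is the mean of the participating hospitals' fee
schedule, rounded half-up to whole dollars (fee schedules are quoted in
whole dollars); both costs convert to USD at a single configured rate
(default 1.33 SGD/USD, 2022) rounded half-up to cents.

Total cost multiplies each draw's episode total by the unit amount, so
cost intervals inherit the projection's percentile construction.
Benchmark savings cost only the episodes above a reference admission rate
(default 40 per 100,000 per year): per draw and year,
$\max(0, N(y) - b \cdot P_y / 10^5)$, summed and priced. The headline
percentage reduction is $100 \times$ savings median / total-cost median;
it cancels the unit cost exactly and is invariant to it. No discounting is
applied by default (a configurable annual rate exists for exploration),
and the only currency conversion is the single fixed rate — no
time-varying exchange or inflation paths.

## The synthetic-data generator

Ground-truth series mirror the fitted model by construction: piecewise
log-linear per-person rates with 0–2 change points, Poisson noise, and an
optional single-year shock that redraws a year's count at a reduced mean
(default multiplier 0.5, emulating a pandemic-style ~50% utilisation
drop). The bundled preset produces a 1994–2020 hospitalisation-like
series: population growing from 3.5M, rates near 80 per 100,000 with one
change point in 2003 where a 4%-per-year decline flattens into 1.7%
annual growth, and a halved 2020 — about 25 usable observations, the size
regime the fitter targets.

What passing tests on these data *show*: the search finds the exact
likelihood optimum (verified against brute-force enumeration), recovers
planted change points, attains near-nominal bootstrap coverage, and the
pipeline's scenario and costing arithmetic is correct. What they *cannot*
show: robustness to overdispersion, autocorrelated surveillance artefacts,
coding changes, or age-structure drift, none of which the generator
emulates — real registry series have all four. Synthetic rates are crude
rates; no age/sex standardisation is modelled.

## Study sizes used in the checks

The statistical acceptance checks run at sizes chosen to make Monte-Carlo
error small relative to the bands being checked while keeping the suite
quick to run routinely: 200 replicate series for change-point recovery and
null selection; 50 random small series (n ≤ 15, up to 2 changes) for the
brute-force equivalence check; 200 replicates × 500 bootstrap iterations
for slope coverage, with the no-change model class (`max_changepoints =
0`) matching the no-change truth those replicates are drawn from — the
coverage claim concerns the bootstrap machinery, not model selection.

## Known limitations

- **BIC overselection at short series.** With ~25 annual observations, the
  exhaustively-searched likelihood gain of a spurious change point is the
  maximum of many correlated $\chi^2_2$-like improvements, and the
  $3\log n$ BIC penalty leaves roughly an 8–9% false-positive rate on
  no-change series (our null-selection study measures ≈91% correct $k=0$
  selection). This is a property of BIC at this $n$, independent of count
  magnitude. Users wanting stricter parsimony can lower
  `max_changepoints` or raise `min_segment_len`; we kept the standard BIC
  definition rather than inventing a stiffer ad-hoc penalty.
- **No overdispersion.** Real utilisation series are often
  extra-Poisson; a negative-binomial variant would widen intervals.
- **Demography is emulated, not modelled.** The recurrence has no age
  structure, so scenarios are trajectory families, not forecasts.
- **Integer-year change points only**, and a single series at a time — no
  joint fitting of admissions/ED/mortality.

## Worked example

```{r example, eval = FALSE}
preset <- synthetic_preset(seed = 1)
fit <- fit_segmented_poisson(preset$series, excluded_years = 2020)
fit
draws <- bootstrap_fit(preset$series, fit, n_iterations = 1000, seed = 1)
trend_estimate(fit, draws)
proj <- compare_scenarios(draws, preset$populations, years = 2023:2040)
dplyr::bind_rows(lapply(proj, glance))
cost <- benchmark_savings(proj$base, preset$populations$base,
                          benchmark_rate_per_100k = 40,
                          hospitalisation_unit_cost())
cost
```

The README shows this session with its printed output; `autoplot()`
methods on the fit and on each projection summary draw the observed and
fitted rates and the credible ribbons.
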