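Package: burdenproj
Title: Change-Point Poisson Trends and Burden Projection for Annual
    Acute-Care Episode Series
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Fits segmented log-linear Poisson models with unknown
    integer-year change points to annual series of acute-care episodes
    (hospitalisations, emergency-department attendances, deaths), with a
    log-population offset so coefficients describe per-person rates and
    with configurable year exclusions (e.g. a pandemic-affected year).
    Propagates uncertainty in the final stable trend by parametric
    bootstrap of the joint (change year, intercept, slope) distribution,
    projects future episode counts under demographic scenarios that vary
    natural growth and net migration, and converts projected episodes
    into costs with unit-cost construction, currency conversion and
    benchmark-capped savings.  Includes a synthetic-data generator with
    known ground truth (piecewise log-linear rates, Poisson noise,
    single-year shocks) so the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
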