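Package: panelsample
Title: Representative Longitudinal and Cross-Sectional Samples from Annual
    Claims Populations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for drawing annual samples of a dynamic beneficiary
    population that are simultaneously valid for cross-sectional analysis
    (each year representative of that year's population) and longitudinal
    follow-up (maximal retention of previously sampled members). Implements
    stratified allocation with county minimums and smooth minority
    oversampling, simple random sampling within county-by-race strata,
    year-over-year retention with weighted fill-in draws from the newly
    eligible frame, Horvitz-Thompson weighting with finite-population
    correction, Taylor-series (linearization) variance estimation, and
    design-based comparisons of weighted samples against known population
    values. Includes a seeded synthetic population simulator emulating the
    statistical structure of Medicare beneficiary summary files so the whole
    pipeline can be exercised without restricted data.
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
    tidyr
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
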