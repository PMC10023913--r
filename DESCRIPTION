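Package: lagcausal
Title: Lagged Causal Effects of Environmental Exposures on Daily Visit Counts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Estimates short-term lagged causal effects of daily air-pollutant
    and meteorological exposures on daily clinical visit counts. Implements
    Spearman lag screening of candidate exposures, causal directed acyclic
    graphs with d-separation and backdoor adjustment-set identification,
    backdoor-adjusted Poisson outcome models with per-unit and
    interquartile-range-scaled effects across lags, a refutation suite
    (random common cause, placebo treatment, data subsets), and attribution
    of multi-year changes in visit counts to pollutant concentration
    declines. Includes a synthetic-data generator with known ground-truth
    effects for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
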