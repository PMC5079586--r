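Package: lenstock
Title: Length-Based Assessment of Data-Limited Fish Stocks
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for assessing data-limited fisheries from per-fish landing
    lengths: Froese catch-composition sustainability indicators (maturity,
    optimum-length interval, mega-spawners), a length-based Spawning Potential
    Ratio (LB-SPR) per-recruit engine with growth-type groups and maximum
    likelihood estimation of relative fishing mortality and gear selectivity,
    Chapman-Robson catch-curve mortality with bias-corrected total mortality,
    generational turnover, and year-trend models (binomial GLMs for indicator
    proportions, a random-intercept model of landed length with parametric
    bootstrap testing). Includes an equilibrium age-structured simulator of
    length compositions so every estimator can be checked against known truth.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    tools,
    yaml,
    lme4
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
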