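Package: knownfate
Title: Known-Fate Radiotelemetry Survival Analysis with Trend and
    Discontinuity Detection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for known-fate survival analysis of radio-collared
    wildlife. Aggregates collar histories into radio-days and death counts
    over arbitrarily anchored 12-month statistical years with age-class
    graduation accounting, imputes deaths of unknown cause proportionally
    to known causes, computes daily and yearly survival with
    normal-approximation confidence intervals, fits weighted linear trends
    to annual daily hazard, scans statistical-year anchors by residual
    standard error, and detects sharp level shifts in the hazard trend by
    regression-discontinuity scans over candidate monthly cutoffs. Includes
    a seedable generator for synthetic collar histories with
    piecewise-constant cause-specific hazards and known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    sandwich,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
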