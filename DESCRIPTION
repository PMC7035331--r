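Package: standspat
Title: Spatial Point-Pattern Analysis of Tree Mortality in Mapped Forest Stands
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing mapped stem data from fixed-area forest plots:
    pair correlation function estimation with translation edge correction on
    rectangular windows, bivariate cross-pattern association, a
    survival-probability-by-distance statistic for marked (live/dead) patterns,
    Monte-Carlo null models (complete spatial randomness, independence, random
    labelling) with rank simulation envelopes and a goodness-of-fit rank test,
    logistic survival modelling with optional plot-level random intercepts,
    exact binomial median tests, and a seeded synthetic stand generator with
    clustered recruitment and random, density-dependent or size-dependent
    mortality, including presets emulating the four developmental stages of
    desert riparian poplar (Populus euphratica) forests.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    lme4,
    yaml,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
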