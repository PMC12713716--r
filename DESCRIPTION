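Package: seasonsdm
Title: Seasonal Species Distribution Models with Environmentally
    Profiled Pseudo-Absences and Niche Dynamics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for modelling the seasonal distribution of highly
    migratory pests from monthly environmental layers and thinned
    occurrence records.  Generates pseudo-absences by distance-restricted
    random sampling (RS) or by one-class environmental profiling (RSEP),
    fits per-season binomial mixed models with linear and quadratic
    terms and a year random intercept, performs backward AIC term
    selection, evaluates models by stratified 5-fold cross-validation
    under three thresholding rules, produces monthly habitat-suitability
    maps and response-curve optima summaries, and quantifies niche
    overlap and expansion/stability/unfilling between seasonal periods
    in a kernel-smoothed PCA environment space.  Includes a synthetic
    landscape and virtual-species generator so the whole pipeline can be
    exercised end-to-end with a known truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    MASS,
    lme4,
    e1071,
    geosphere,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pROC,
    glmmTMB
Config/testthat/edition: 3
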