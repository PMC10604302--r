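Package: cardioCS
Title: Non-Invasive Hemodynamic Indicators for Heart-Disease Classification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes seven non-invasive hemodynamic indicators (mean arterial
    pressure as the logarithmic mean of systolic and diastolic pressure, the
    resistance-compliance time constant of an exponential pressure-decay model,
    the pulsatile blood pressure index and its resistance-compliance ratio, a
    Kepler-inspired harmony measure, and the triangular-wave ejection-time
    fraction with its negative-log transform) from cuff-style vital signs, ranks
    them between cardiac and non-cardiac groups with a variance-standardised
    consistency measure and Wilcoxon-Mann-Whitney tests, and evaluates their
    diagnostic value through feature selection (information gain, variance
    inflation factor, analysis of variance, stepwise AIC) and repeated-holdout
    classification with naive Bayes, random forests, logistic regression,
    boosted trees, and support vector machines. Includes a seeded synthetic
    cohort generator emulating the UCI heart-disease subsets so the whole
    pipeline is testable without external downloads, plus a reader for the raw
    76-attribute UCI heart-disease file dialect.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    e1071,
    randomForest,
    rpart
Suggests:
    testthat (>= 3.0.0),
    withr,
    car,
    jsonlite,
    optparse
Config/testthat/edition: 3
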