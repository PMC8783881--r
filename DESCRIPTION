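Package: grainscore
Title: Nutri-Score Nutrient Profiling with a Whole-Grain Modification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A configurable implementation of the Nutri-Score (FSA-NPS derived)
    points-based nutrient profiling algorithm, extended with a whole-grain
    component that awards up to -5 beneficial points to solid foods on a
    non-linear sliding scale of whole-grain content expressed as a percentage
    of food dry matter. Computes per-food component points, nutritional
    scores and A-E classes under both the original and the modified
    algorithm; aggregates food scores into energy-weighted whole-diet
    nutritional scores from single-day dietary intake records; and provides
    the evaluation statistics used to compare the two algorithms
    (component-score rank correlations, class-transition tables, correlation
    with external diet-quality indices, and quantile analysis of whole-grain
    intake density). A seeded generator of synthetic food-composition and
    dietary-survey tables makes every stage testable without access to
    national databases.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
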