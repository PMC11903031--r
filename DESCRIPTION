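Package: zdiffr
Title: Longitudinal Change Scores from Pre-Trained Normative Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Evaluates intra-individual longitudinal change in image-derived
    phenotypes (e.g. regional cortical thickness) against a normative model
    pre-trained on cross-sectional data. Implements warped Bayesian linear
    regression normative modelling (B-spline age basis, site dummies,
    sinh-arcsinh likelihood warping), adaptation of a pre-trained model to a
    new scanner site using local healthy controls, the calibrated z-diff
    score for between-visit change together with its longitudinal
    noise-variance estimator, region-wise group testing with
    Benjamini-Hochberg correction, a detection-power simulation over
    disruption size and residual autocorrelation, and a synthetic-cohort
    generator so the full pipeline runs without any data download.
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
    jsonlite,
    purrr,
    rlang,
    splines,
    stats,
    tibble,
    tidyr
Suggests:
    optparse,
    readr,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
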