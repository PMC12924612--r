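Package: rocsize
Title: Power and Sample Size for Comparing Two Correlated ROC Curves
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Analytic power and sample-size calculations for paired
    diagnostic-accuracy studies that compare the areas under two correlated
    receiver operating characteristic (ROC) curves. Implements the
    Obuchowski-McClish variance formulas for discrete (rating) data under the
    binormal model, the Hanley-McNeil variance formulas for continuous data
    with a reference grid mapping inter-test score correlations to ROC-area
    correlations, dropout-inflated enrollment arithmetic, factorial scenario
    grids with power curves, and a seeded Monte-Carlo validator of achieved
    power based on simulated paired binormal scores.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports: stats, utils, graphics, jsonlite
Suggests: testthat (>= 3.0.0), optparse, withr
Config/testthat/edition: 3
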