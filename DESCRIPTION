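Package: rmtlcr
Title: Restricted Mean Time Lost for Competing Risks Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Author: Package Author [aut, cre]
Maintainer: Package Author <author@example.org>
Description: Nonparametric estimation and inference for the restricted mean
    time lost (RMTL) under competing risks: Aalen-Johansen cumulative
    incidence estimation with pointwise variance, RMTL and restricted mean
    survival time (composite endpoint) with closed-form variances and
    confidence intervals, a normal-approximation two-sample test (Diff) and a
    supremum-type two-sample test (sDiff) referred to the distribution of the
    supremum of absolute standard Brownian motion, sample-size formulas for
    both tests (the sDiff inflation factor solved by safeguarded
    Newton-Raphson on the drifted Brownian-motion power equation), and a
    piecewise-Weibull competing-risks simulator with calibrated uniform
    censoring for type-I error, power and sample-size calibration studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    survival,
    cmprsk,
    jsonlite,
    withr
Config/testthat/edition: 3
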