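Package: isrfit
Title: Inference of Insulin and C-Peptide Secretion Rates from Sparse OGTT Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Model-based estimation of the glucose-dependent insulin secretion
    rate (ISR) and c-peptide secretion rate (CSR) from sparse oral glucose
    tolerance test (OGTT) measurements. A sigmoid secretion functional drives
    single- or two-compartment first-order clearance models; the unknown
    parameters (maximum secretion rate, glucose midpoint, sigmoid width and
    plasma/interstitial degradation times) are recovered by multi-start
    bounded nonlinear least squares with Levenberg-Marquardt refinement, with
    ensemble (bootstrap-over-initialization) uncertainty quantification.
    Includes goodness-of-fit metrics, validation of the expected 1:1 molar
    ISR:CSR coupling, hepatic extraction estimation from the CSR~ISR slope,
    leave-one-timepoint-out outlier screening, and a synthetic OGTT generator
    for parameter-recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    minpack.lm,
    Matrix,
    jsonlite,
    stats,
    utils
Suggests:
    deSolve,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
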