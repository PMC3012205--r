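Package: fertbias
Title: Ascertainment Bias in Family-Based Fertility Estimates of Schizotypy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analytic and simulation tools for quantifying the ascertainment
    bias that arises when the fertility associated with schizotypy is
    estimated from schizophrenic patients and their relatives. Implements
    the Bayes posterior on family fitness class given a diagnosis, the true
    and ascertainment-distorted mean relative fertility of schizotypal-family
    members, the resulting underestimation bias and the condition under
    which neutral or positive selection is misread as negative selection.
    Includes a forward simulator of family populations with fitness classes,
    proband-based ascertainment of simulated families, Monte-Carlo
    validation of the closed forms, and parameter sweeps mapping the
    misclassification region.
License: MIT
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    ggplot2
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
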