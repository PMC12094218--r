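Package: cosinorpower
Title: Power Analysis for Cosinor Rhythm Detection Under Arbitrary Sampling Designs
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Analytic power analysis for the standard cosinor model used to
    detect biological (e.g., circadian) rhythms. Computes the noncentrality
    parameter of the rhythm-detection F test correctly for arbitrary sampling
    designs, including non-centered and unevenly spaced measurement schedules,
    via the population variance of the phase-shifted cosine regressor. Also
    provides the general Frisch-Waugh-Lovell orthogonalization machinery that
    extends the noncentrality parameter to cosinor models with nuisance
    covariates (trends, blocks), design diagnostics (centeredness, phase
    invariance), an intentionally reproduced uncentered-quadratic-form
    noncentrality parameter for comparison, Monte Carlo validation of power
    and type-I error, sample-size solvers, and a command-line interface.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
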