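Package: kappamcc
Title: Coherence Diagnostics for Cohen's Kappa and the Matthews
    Correlation Coefficient
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Chance-corrected agreement statistics for square confusion
    matrices: Accuracy, chance agreement, Cohen's Kappa and the
    multi-class Matthews Correlation Coefficient (MCC), computed both in
    closed form and through an independent indicator-matrix correlation
    oracle.  Provides the parametric confusion-matrix families used to
    study regimes where Kappa moves against the quality of the
    classification (a worse classifier scoring a higher Kappa), two
    structural diagnostics -- Frobenius asymmetry and base-2 Shannon
    entropy of the off-diagonal cells -- and a sweep engine that locates
    Kappa's interior minima, verifies closed-form relations between the
    two statistics, and classifies each family into the
    agreement/disagreement regime determined by whether the off-diagonal
    entropy decreases to zero.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
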