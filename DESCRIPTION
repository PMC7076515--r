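Package: mucodiff
Title: Drug Diffusivity in the Presence of Mucin from Localized
    UV-Visible Spectroscopy
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Quantifies drug diffusion coefficients from time-absorbance
    traces recorded at a fixed height in a cuvette (localized UV-visible
    spectroscopy), by nonlinear least-squares fitting of the closed-form
    solution of Fick's second law for a half-Gaussian source.  Includes a
    finite-difference reference solver used to validate the closed form
    inside its short-time regime, derived mucin-interaction statistics
    (relative diffusivity, percentage reduction, inverse-diffusivity
    linearity, injected-amount mass balance, Stokes-Einstein radii),
    apparent-permeability computation for acceptor-replacement permeation
    assays such as the mucus-PVPA, and seeded synthetic-data generators
    with known ground truth for parameter-recovery studies.
License: MIT
Encoding: UTF-8
Imports:
    minpack.lm,
    stats,
    utils,
    graphics,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
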