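Package: epidtransit
Title: EPID Transit In Vivo Dosimetry for Tangential Breast Irradiation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reconstructs the in vivo dose delivered during tangential breast
    irradiation from electronic portal imaging device (EPID) transit signals.
    Implements the correlation-function calibration F(w) between transit signal
    and midplane dose, the linear scatter factor f(d,r), radiological path-length
    ray tracing through a 2D density slice, midpoint and full-profile dose
    reconstruction with inverse-square and attenuation corrections, correction of
    patient setup misalignment by 1D portal-image profile alignment, and QA
    reporting against tolerance levels derived by quadrature uncertainty
    propagation. A seeded simulator provides cylindrical water phantoms and a
    breast-shaped slice with a low-density lung region so the whole chain is
    testable without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
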