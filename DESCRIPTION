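Package: avianEIT
Title: Electrical Impedance Tomography Analysis of Avian Air-Sac Ventilation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for thoracic electrical impedance tomography (EIT) in birds:
    a chicken coelom phantom built from body, lung and cardiac contours, a 2-D
    finite-element forward model with a 32-electrode belt, GREIT difference-image
    reconstruction, breath segmentation and tidal impedance variation, centre of
    ventilation and regional ventilation distribution, classification of
    expiratory breathing-pattern morphology (BrP1-4), an exact Fisher test for
    r x c contingency tables, and a seeded simulator of cranial-air-sac
    ventilation with isovolumetric lungs and cardiac flutter for end-to-end
    validation of the pipeline.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    Rcpp,
    signal,
    pracma,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0), optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
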