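Package: paleopH
Title: Boron-Isotope Paleo-pH Reconstruction from Coralline Algae
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Reconstructs historical surface seawater pH from boron isotope
    (delta-11-B) measurements of annually banded crustose coralline algae.
    Provides a total-scale seawater carbonate-system solver (Lueker carbonic
    acid constants, Dickson boric acid constant), the species-calibrated
    delta-11-B to pH conversion with full Monte-Carlo uncertainty propagation,
    B/Ca-based screening of diagenetically contaminated sub-samples,
    calendar-year assignment from seasonal Mg/Ca cycles, conservative
    water-mass and river-seawater mixing models with carbonate-system pH
    evaluation, and a forward model that generates complete synthetic
    coralline-algae datasets from a prescribed pH history for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
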