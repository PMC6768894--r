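Package: radonskin
Title: Biokinetic Modelling of Radon Uptake Through the Skin from Thermal Water
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Compartmental biokinetic model of radon transfer from thermal
    bath water through the skin into blood, organs and exhaled breath. The
    model extends a whole-body noble-gas circulation model with dermal and
    subcutaneous skin compartments split into water-exposed and air-exposed
    chains, time-dependent skin permeability and skin blood flow during
    immersion (temperature ramp and stratum-corneum swelling), instrument
    dead-space dilution of single-breath samples, the radon-transfer
    statistic, per-subject estimation of the skin permeability coefficient,
    and a synthetic-data generator reproducing the statistical structure of
    bathtub exhalation measurements.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    Matrix,
    yaml,
    jsonlite,
    stats,
    utils,
    tools,
    graphics
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
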