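Package: pennesflow
Title: Steady-State Bio-Heat Modeling of Thermal Massage and Predicted
    Circulation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Voxel-based steady-state solver for the Pennes bio-heat
    equation on a synthetic layered phantom of the human lumbar back,
    coupled to an empirically calibrated sigmoidal model of
    temperature-dependent blood flow.  Simulates contact heating by a
    thermal massage bed (a 40 degree C mat plus four heated actuator
    discs), extracts depth and lateral temperature profiles, sweeps
    actuator settings from 45 to 65 degrees C, and predicts the resulting
    fold-change in local circulation.  Includes analytic and
    manufactured-solution oracles for solver verification.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    rlang,
    stats,
    utils,
    yaml
Suggests:
    minpack.lm,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
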