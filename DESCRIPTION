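Package: coventr
Title: Model-Based Patient Matching and Settings for In-Parallel Co-Ventilation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Decision-support tools for co-mechanical ventilation (Co-MV), in
    which two fully sedated patients share one ventilator in parallel under
    pressure-control mode. Implements a single-compartment linear lung model
    (elastance E, resistance R) for forward simulation of pressure-controlled
    breaths and tidal-volume prediction, identification of respiratory
    mechanics from measured pressure/flow waveforms by multiple linear
    regression, resistance-elastance tidal-volume safe-zone maps for candidate
    screening against a 6-8 mL/kg target, and a double-compartment shared-
    circuit model with iterative peak-inspiratory-pressure tuning to recover
    each patient's desired tidal volume. Includes a virtual-patient cohort
    generator and an end-to-end screening-and-tuning protocol.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    deSolve,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
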