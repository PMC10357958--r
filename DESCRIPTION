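Package: electrode
Title: Electrode-Tissue Interface Modeling and Stimulation Safety Limits
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Models the electrochemical interface between neural recording and
    stimulation contacts and the surrounding tissue.  Provides constant-phase-element
    (CPE) equivalent circuits, complex nonlinear least-squares fitting of impedance
    spectra, fractional-order simulation of current-clamped pulse transients, an
    empirical excursion-potential model with its closed-form current-injection
    limit and diameter scaling, Shannon's equation for comparison, charge-per-phase
    and charge-density pulse safety checks, and recording-side figures of merit
    (coupling coefficient, thermal noise, conduction delay, crosstalk, acquisition
    data rate).  Includes seeded synthetic-data generators for noisy impedance
    spectra and excursion datasets, columnar text and JSON file formats, and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    grDevices,
    jsonlite,
    minpack.lm,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
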