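Package: kincoex
Title: Kin-Bacteria Coexistence Under Pulsed Antibiotic Perturbation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Simulates cooperator-cheater-regulator bacterial communities
    with a modified Lotka-Volterra competition model that includes Allee
    terms and time-windowed, density-dependent antibiotic mortality.
    Provides a serial-dilution batch-culture protocol engine, an
    operational coexistence classifier, two- and three-member phase-diagram
    sweeps, estimators for plate-reader growth curves and colony counts,
    and a synthetic-data generator for parameter-recovery testing.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    deSolve,
    stats,
    utils,
    graphics,
    grDevices,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
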