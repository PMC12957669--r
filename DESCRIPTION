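Package: capnovol
Title: Volumetric Capnography Analysis and Synthetic Breath Simulation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Per-breath analysis of synchronized respiratory airflow and
    sidestream CO2 recordings: capnometer transport-delay correction, flow
    integration and breath segmentation, construction of volumetric
    capnograms (CO2 partial pressure against cumulative expired volume),
    phase-2 and phase-3 slope estimation with end-tidal normalization, and
    dead-space fractions after Fowler, Bohr, and Enghoff together with
    intrapulmonary shunt indices. Includes a synthetic-recording generator
    that emulates positive- and negative-pressure ventilation expiratory
    flow patterns, sidestream sensor delay and smoothing, and measurement
    noise, with an independent numeric oracle for every index so the whole
    pipeline is testable without animal data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    signal,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
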