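Package: icudea
Title: Severity-Adjusted Benchmarking of Intensive Care Units with Data
    Envelopment Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for benchmarking intensive care units (ICUs) from
    patient-level admission data. Computes severity-adjusted performance
    metrics - the standardized mortality ratio (SMR) from the SAPS-3
    hospital-mortality equation and the standardized resource use (SRU)
    with ICU length of stay as the resource surrogate - and scores units
    with variable-returns-to-scale (BCC) data envelopment analysis in
    input or output orientation, handling undesirable variables by
    reciprocal transformation. Provides two-phase slack maximization,
    peer sets, reference counts and frontier projection targets for
    non-efficient units, the classical SMR-by-SRU efficiency-matrix
    quadrants, grouped efficiency summaries, a calibrated synthetic
    cohort generator with a planted-frontier mode for validation, and a
    configuration-driven analysis pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
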