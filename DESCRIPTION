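Package: hemowss
Title: Cycle-Resolved Wall Shear Stress Indicators and Vessel Morphometrics
    for Pulsatile Hemodynamics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Tools for post-processing time-resolved wall shear stress (WSS)
    vector fields on triangulated vessel surfaces. Computes the standard
    cycle-averaged hemodynamic indicators (TAWSS, OSI, RRT, TransWSS, OSItr),
    classifies low/normal/high shear zones, and quantifies whether the
    near-wall flow washes the wall axially or circumferentially. Includes
    exact Womersley solutions and an independent Crank-Nicolson solver for
    pulsatile Newtonian flow in a rigid tube, aortic-like inflow waveform
    synthesis with Reynolds-number bookkeeping, branch-angle and
    hydraulic-diameter morphometrics, outlet flow-split accounting, and a
    seeded synthetic-data generator producing surface WSS series with known
    ground truth.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    Matrix,
    methods,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    igraph,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
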