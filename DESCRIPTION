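Package: chipvasc
Title: Quantification and Flow Modelling for Microvascular Networks on
    Microfluidic Chips
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Analysis stack for stromal-cell-supported microvascular
    networks grown in gravity-perfused microfluidic chips. Implements a
    closed-form and numerical model of reservoir-driven interstitial flow
    with resistance calibration and flow-duration estimation, image-based
    tracking of a fluorescent flow front with conversion to velocity and
    flow-rate series, vessel-network morphometry (area fraction, skeleton
    length, mean diameter) and pericyte-coverage quantification from
    binary masks, relative qPCR quantification by the 2^-ddCt method with
    hierarchical clustering, unpaired t-tests and the two-stage step-up
    false-discovery-rate procedure, plus seeded synthetic-data generators
    for every stage so the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    EBImage,
    tiff,
    jsonlite,
    yaml,
    rlang,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
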