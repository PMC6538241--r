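Package: discmech
Title: Biomechanical Parameter Extraction for Intervertebral Disc Motion-Segment Tests
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Extracts the standard biomechanical outcome parameters from ex vivo
    intervertebral-disc motion-segment tests: range of motion, compressive and
    tensile stiffness, and an adaptive moving-window neutral-zone fit from cyclic
    axial force-displacement records; torsional stiffness, torque range and the
    torsional neutral zone from torque-rotation records; effective failure stress
    and failure-mode classification from compression-to-failure ramps; and
    radiographic disc height from digitized endplate profiles. A synthetic
    motion-segment simulator with an analytically known logistic-blended trilinear
    constitutive law provides ground-truth hysteresis loops, failure ramps,
    endplate geometry and whole study cohorts, so every analysis stage is testable
    by parameter recovery. Includes a study pipeline reproducing the paired
    intact-to-treated normalization design used in cadaveric and large-animal
    disc-repair studies.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
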