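Package: trapflow
Title: Microvortex Trap Design, Creeping-Flow Simulation and Fluorescence
    Velocimetry for Biofilm Microfluidics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying biofilm formation in shallow microfluidic
    channels decorated with vortex-generating microstructures (nested-funnel
    microtraps and arrow arrays). Builds rasterized channel/feature depth maps,
    solves depth-averaged (Hele-Shaw) creeping flow and vertical-slice Stokes
    flow, derives vorticity and Q-criterion vortex metrics and streamlines,
    advects Brownian tracer particles, generates synthetic fluorescence
    microscopy videos and biofilm images with ground truth, recovers velocities
    by particle tracking velocimetry (PTV) and particle image velocimetry
    (PIV), and quantifies biofilm localization (wall/corner/cavity occupancy,
    intensity profiles, regime classification).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    yaml,
    tiff,
    EBImage,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
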