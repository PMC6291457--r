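Package: ajdyn
Title: Adherens Junction Length and Straightness Dynamics During
    Epithelial Contraction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Quantitative analysis of adherens junction length control
    during epithelial tissue contraction, as in Drosophila dorsal
    closure. Provides junction geometry metrics (path length,
    inter-vertex distance, straightness) from polylines or segmented
    label images, interval-based estimation of junction removal and
    contraction rates, a straightness ODE model with a sigmoid
    removal-rate law (fixed point, relaxation timescale, trajectory
    integration, sigmoid fitting), a scaled-average-cell (SAC) pipeline
    for shape-normalised radial intensity profiling of myosin and
    E-cadherin distributions, laser-ablation recoil analysis by
    single-exponential fitting, and seeded synthetic-data generators
    (ruffled polylines, contracting junction ensembles, segmented
    multi-channel cell movies, recoil traces) that emulate the imaging
    the analysis consumes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    deSolve,
    minpack.lm,
    EBImage,
    tiff,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
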