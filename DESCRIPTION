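Package: neuroscreen
Title: Dual-Endpoint In Vitro Neurotoxicity Screening from Microelectrode
    Arrays and Neurite Morphometry
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end, simulation-validated pipeline for in vitro
    neurotoxicity screening with two endpoint families.  The
    electrophysiology branch turns raw multi-well microelectrode-array (MEA)
    voltage recordings into per-electrode spike trains (band-pass filtering,
    adaptive per-electrode thresholding at a multiple of the local noise
    standard deviation) and per-well network metrics (firing rate,
    ISI-threshold bursts, synchrony index, normalized multiinformation).
    The morphometry branch quantifies six neurite-outgrowth phenotypes
    (maximum and total neurite length; numbers of roots, nodes, extremities
    and segments) from two-channel fluorescence images via segmentation,
    skeletonization and soma-rooted graph analysis.  A statistics layer
    provides baseline normalization, one-way ANOVA with Dunnett many-to-one
    comparisons, direction-of-effect classification over dose and time, and
    relative qPCR quantification (delta-delta-Ct).  A synthetic-data module
    generates recordings and neuron images with exact ground truth so every
    stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    EBImage,
    igraph,
    mvtnorm,
    jsonlite,
    tiff,
    data.table,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    multcomp,
    withr,
    optparse
Config/testthat/edition: 3
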