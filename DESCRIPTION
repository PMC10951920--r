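Package: gliotrack
Title: Single-Particle Tracking Analysis of Membrane Protein Mobility in
    Oligodendrocytes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for single-particle tracking (SPT) analysis of sparse
    photoswitched fluorophores in live-cell time-lapse imaging, motivated by
    studies of myelin basic protein (MBP) mobility across oligodendrocyte
    maturation stages. Provides trajectory simulation with Brownian, confined
    and directed motion models plus localization noise and photobleaching;
    synthetic movie rendering; spot detection and greedy nearest-neighbour
    linking; per-track mean-squared-displacement curves, diffusion
    coefficients, confinement ratios and per-cell motion-profile circularity;
    pooled-range frequency binning; and the nonparametric statistical layer
    (Kolmogorov-Smirnov, Kruskal-Wallis, Dunn's post hoc) used to compare
    particle populations between conditions.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    tiff,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    ggplot2,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
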