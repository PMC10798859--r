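Package: runpause
Title: Single-Molecule Motor Kinetics and Cargo Run-Pause Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis of single-molecule motor-protein imaging
    experiments in living cells. Provides stochastic generators for
    microtubule binding events, run-and-pause cargo trajectories, fluorophore
    photobleaching and synthetic HILO-style movies with ground truth; spot
    detection, nearest-neighbour track linking, intensity measurement and
    kymographs; whole-track classification against a nucleus (minus-end)
    reference and run/pause segmentation of cargo trajectories; kinetic fits
    (exponential residence survival, constrained two-Gaussian intensity
    mixtures for fluorophore counting, mean squared displacement,
    photobleaching decay); object-based colocalization with a flipped-channel
    control; and population transport summaries (motile fractions, net speed,
    delivery-time estimates, Fisher exact comparisons).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite,
    igraph,
    minpack.lm,
    tiff,
    EBImage
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
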