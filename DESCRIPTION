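Package: trajseg
Title: Sliding-Window 1D U-Net Segmentation of Particle Trajectories
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Per-point segmentation of single-particle tracking trajectories
    into moving (directed motion) and not-moving (stalled, Brownian, confined)
    classes. Trajectories are cut into fixed-length sliding windows, each
    window is origin-normalized and optionally converted to polar coordinates,
    segmented by a small 1D U-Net (implemented in base R with seeded
    deterministic training via Adam and binary cross-entropy), and the
    overlapping per-window probabilities are stitched back onto the original
    points. Includes a synthetic vesicle-motion simulator (directed, Brownian,
    confined, stalled regimes with a switching process), an evaluation module
    using point accuracy with the first point of each track excluded, and a
    coordinate-system comparison experiment.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, tools, yaml, jsonlite
Suggests: testthat (>= 3.0.0), withr, optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
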