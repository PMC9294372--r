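Package: caimtools
Title: Trial-Based Calcium Imaging Registration, Segmentation, and
    Cross-Session Tracking
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for processing trial-structured two-photon calcium
    imaging movies: fast integer-translation motion correction by FFT
    cross-correlation against a template, two online statistical
    algorithms for identifying active-neuron regions of interest (ROIs)
    from a single trial (cumulative dF/F with Renyi-entropy
    auto-thresholding, and a binarized sensitivity index with exponential
    run amplification), integration of per-trial masks into a session
    mask, rigid/affine alignment of repeated imaging sessions with
    capture-all ROI unification, and per-ROI dF/F trace extraction with
    activity classification. A seeded synthetic-movie generator
    (heartbeat-like shift simulation and planted Gaussian-profile cells)
    provides ground truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    jsonlite,
    stats,
    tiff,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
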