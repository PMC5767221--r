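Package: bretr
Title: Ratiometric BRET Image Analysis Pipeline
Version: 1.0.0
Authors@R: person("bretr", "maintainers", email = "bretr@example.org", role = c("aut", "cre"))
Description: A scriptable pipeline for ratiometric bioluminescence resonance
    energy transfer (BRET) imaging. Cleans donor/acceptor luminescence
    time-lapse stacks (3x3 median filter, per-frame median background
    subtraction, translation-only subpixel registration), masks the donor
    channel with a composite adaptive threshold that tracks the specimen
    across heterogeneous intensities and donor decay, computes the pixel-wise
    acceptor/donor ratio, renders it on a bounded 16-color pseudocolor scale,
    and quantifies ratio mean and standard deviation in regions of interest
    over time, excluding zero (background) pixels. Includes a deterministic
    neuron-like phantom generator with ground truth for validation, a minimal
    uncompressed multi-page TIFF reader/writer, JSON region sidecars, and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
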