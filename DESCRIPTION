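Package: reconqa
Title: Spatially Resolved Quality Assessment of MRI Reconstruction Methods
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Objective, spatially resolved quality assessment for MRI
    reconstruction methods. Computes per-pixel local point-spread-function
    (LPSF) resolution maps and pseudo multiple-replica g-factor (noise
    amplification) maps for arbitrary reconstruction operators, together
    with the synthetic multi-coil acquisitions, Cartesian undersampling
    masks, and reference reconstructions (RSS inverse FFT, zero-filled,
    GRAPPA, total-variation-regularized compressed sensing via ADMM)
    needed to exercise the framework end-to-end without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    ggplot2,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
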