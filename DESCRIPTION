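Package: dendrosmooth
Title: Fast Spatiotemporal MAP Smoothing of Calcium Signals on Dendritic Trees
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for single-trial spatiotemporal smoothing of calcium
    indicator fluorescence recorded at sparse, user-chosen locations on a
    dendritic tree (random-access multi-photon scan data). The relative
    concentration of calcium-bound indicator across the whole tree is
    modelled as a time-varying linear combination of locally supported
    spline bumps placed along the tree, whose hidden weights follow
    first-order autoregressive decay driven by nonnegative sparse
    innovations (calcium transients from backpropagating action potentials
    or synaptic input). The maximum a-posteriori trajectory under an
    exponential innovation prior is computed by a log-barrier
    interior-point method whose Newton step exploits the block-tridiagonal
    Hessian, giving cost linear in the number of time bins. Includes SWC
    morphology handling, tree pruning to imaged subtrees, data-driven
    estimation of every model parameter (baseline, decay constant, spline
    spacing and amplitude prior via nonnegative least squares, noise
    variance, event-rate schedule), a gamma photomultiplier noise model,
    and a synthetic-experiment generator.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Matrix,
    pracma,
    jsonlite,
    yaml,
    stats,
    graphics,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr,
    igraph
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
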