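Package: img2net
Title: Network Extraction from Raster Images via Optimal Transport Dynamics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Extracts weighted spatial graphs from raster images of
    network-like subjects (retinal vessels, slime mould, river beds).
    Supra-threshold pixels become nodes of an 8-connected pixel-adjacency
    graph on which Physarum-inspired adaptation dynamics (a dynamic
    Monge-Kantorovich routing optimization) consolidate an imaginary flow
    of colour mass; the stationary conductivities select the edges and
    provide principled edge weights. Loops are recovered by superposing
    filtered trees from several single-source runs. Includes a minimum
    spanning tree plus Steiner tree baseline, grid-based similarity
    metrics between a network and an image, parametric synthetic scene
    generators with known ground truth, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    igraph,
    png,
    tiff,
    EBImage,
    yaml,
    optparse,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    MASS,
    jsonlite,
    withr
Config/testthat/edition: 3
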