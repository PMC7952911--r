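Package: symspike
Title: Mirror-Symmetry Density via Distance Histograms and Spiking Neural Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Computes the mirror-symmetry density of two-dimensional point
    data: a scalar field assigning every grid location the peak of its binned
    distance distribution to the input points, so that perpendicular
    bisectors and centers of symmetric figures stand out. Provides the
    explicit distance-histogram algorithm and a cycle-accurate
    leaky-integrate-and-fire spiking network with distance-proportional
    delay lines whose coincidence detection reproduces it, plus GPU-style
    heuristics (all-pairs bisector rasterization and randomized midpoint
    voting), hierarchical and recurrent layering through a synchronization
    layer, intra- and inter-set comparison via pseudorandom delay codes, a
    Sobel-based image pipeline with polygon region statistics, and synthetic
    fixture generators (shape outlines, IFS triangle fractal,
    satellite-like tiles with building footprints).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    purrr,
    rlang,
    withr,
    generics,
    ggplot2,
    scales,
    readr,
    mgcv,
    jsonlite,
    png,
    tiff
Suggests:
    testthat (>= 3.0.0),
    optparse,
    patchwork
Config/testthat/edition: 3
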