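Package: lmdist
Title: Local Manifold Adjustment of Beta-Diversity Distances
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Unsupervised correction of oversaturated pairwise beta-diversity
    measures. Community dissimilarities such as Bray-Curtis and Jaccard have a
    bounded dynamic range, so samples far apart on a long ecological gradient
    pile up near the measure's upper bound and ordinations show arch or
    horseshoe artifacts. The package builds a radius-thresholded neighbor
    graph over the samples, repairs connectivity with minimum-spanning-tree
    edges, and replaces every pairwise value by the graph geodesic, letting
    adjusted distances exceed the original measure's range. Includes automatic
    neighborhood-radius selection with a degree filter and an
    ordination-fidelity objective, optional Gaussian smoothing across radii, a
    left-skew oversaturation diagnostic, a Gaussian-coenocline gradient
    community simulator with Dirichlet noise, a Swiss-roll benchmark
    generator, and a command-line interface.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    e1071,
    igraph,
    optparse,
    stats,
    utils,
    vegan
Suggests:
    ape,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
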