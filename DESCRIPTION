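Package: fibrephantom
Title: Growth-Based White-Matter Fibre Phantoms and Morphometry
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Generates dense, non-intersecting three-dimensional white-matter
    fibre phantoms by growing fibres one-by-one on a Delaunay-triangulated
    node network under biologically motivated cost rules (chemoattraction,
    fibre collapse, dynamic network densification, fasciculation), followed
    by a global position relaxation and implicit-surface (metaball) meshing
    with negative potentials that guarantees pairwise non-intersecting
    watertight fibre surfaces. Includes a morphometry suite (centre lines,
    equivalent-diameter profiles, spherical orientation histograms, volume
    fractions, virtual histology with slice-wise shape metrics), Watson and
    elliptically symmetric angular Gaussian direction samplers, PLY export,
    and experiment harnesses for input-versus-output morphology sweeps and
    mechanism ablations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    tibble,
    dplyr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    yaml,
    stats,
    utils,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
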