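Package: svdsurgery
Title: Condition-Number Surgery on Singular Values with Topological
    Profiling of Matrix Point Clouds
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Operators that recondition square matrices by editing the
    lower singular values of their singular value decomposition and
    reconstructing: tail replacement, linear-combination replacement, full
    orthogonalisation, and a threshold-and-smooth operator that enforces a
    condition-number bound while preserving the spectral norm. Includes
    generation of Gaussian random-matrix ensembles, unit-sphere embedding
    of matrix clouds and of their inverse clouds, Vietoris-Rips persistent
    homology in dimensions 0 and 1, death-based binning tables, and
    bottleneck and Wasserstein distances between persistence diagrams.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
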