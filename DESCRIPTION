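Package: crownmap
Title: Spatial Statistics and Persistent Homology for Fossil Hook Assemblages
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to analyse the three-dimensional arrangement of labelled
    hook-like structures preserved inside ammonite body chambers. Provides a
    landmark-based specimen data model, nearest-neighbour morphotype
    composition statistics with analytic random-labelling expectations and
    Tukey-fence outlier exclusion, a self-contained Vietoris-Rips persistent
    homology implementation (dimensions 0 and 1) with minimum-spanning-tree
    link extraction, reconstruction of candidate armature axes from
    morphotype pairings, and a seeded synthetic-specimen generator for
    validation without access to original tomographic data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    igraph,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
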