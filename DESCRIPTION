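Package: chukardemog
Title: Demographic Inference for Chukar Partridge Phylogeography
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Mitochondrial and microsatellite demographic inference for the
    chukar partridge (Alectoris chukar) and similarly structured taxa:
    sequence diversity indices, Kimura two-parameter distances, Tajima's D and
    Fu's Fs neutrality tests, distance-based Phi-ST and Weir-Cockerham F-ST,
    mismatch-distribution analysis under the sudden-expansion model with
    tau-to-calendar-time dating, a coalescent simulator with stepwise and
    generalized stepwise microsatellite mutation, approximate Bayesian
    computation for demographic model choice and parameter estimation with
    pseudo-observed-dataset validation, and Monmonier maximum-difference
    barrier detection on a Delaunay triangulation of sampling sites. Includes
    a synthetic-data generator emulating a 16-population sampling design so
    the whole workflow runs offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    ape,
    deldir,
    jsonlite,
    nnet,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
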