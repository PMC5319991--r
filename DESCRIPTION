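Package: pathmda
Title: Path-Based Prediction of Microbe-Disease Associations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Predicts candidate microbe-disease associations from a sparse
    bipartite catalogue of known associations. Gaussian interaction profile
    kernel similarities for microbes and for diseases are fused with the
    known associations into a heterogeneous weighted network; all cycle-free
    paths up to a length bound between each microbe and each disease are
    enumerated by depth-first search, scored with an exponential length
    decay, and aggregated into a ranked prediction matrix. Includes
    leakage-safe global and local leave-one-out cross-validation, repeated
    k-fold cross-validation with ROC/AUC reporting, a planted-block
    synthetic association generator, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
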