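Package: segentropy
Title: Entropy-Based Evaluation of Single-Cell Segmentation Quality
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Bayesian evaluation of 2-D single-cell segmentation quality for
    multiplexed tissue imaging (IMC, MIBI, CODEX, CycIF). Each segmented
    cell's marker-expression vector is deconvolved into fractional
    contributions from user-specified cell-type profiles via a Dirichlet
    mixture model fitted by Metropolis-within-Gibbs MCMC; the Shannon
    entropy of the inferred contribution vector scores how cleanly a single
    cell type explains the cell, and the average entropy over an image
    scores the segmentation. Includes a forward simulator of expression
    matrices and injectors for partial, split and merge segmentation
    errors, so the method is fully testable without imaging data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics,
    grDevices,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
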