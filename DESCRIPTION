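Package: anninet
Title: Two-Tier Neural-Network Biomarker Screening and Gene Interaction
    Inference
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Screens genes-by-samples expression tables for candidate disease
    biomarkers with exhaustive single-input multilayer-perceptron models
    (1-2-1 backpropagation networks with resampled train/test/validation
    splits and early stopping), ranks genes by signed standard residual
    errors, and selects invariant housekeeping genes.  A second tier infers
    signed gene-gene influence networks by leave-one-gene-out neural-network
    regression (each gene in turn predicted from the remaining panel genes,
    averaged trained weights giving stimulatory or inhibitory edges), detects
    hub genes, expands hubs per disease group, and exports Cytoscape-ready
    networks.  Includes probe-to-gene collapsing, percentile and median
    baseline normalization, the supporting statistics (Welch t-test, one-way
    ANOVA, Benjamini-Hochberg FDR, rank products), a synthetic expression
    data generator with planted ground truth, and a deterministic pipeline
    driver.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
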