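Package: dictydev
Title: Clonal Versus Chimeric Development Analysis for Social Amoebae
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools to compare clonal and chimeric multicellular development
    in Dictyostelium discoideum from bulk RNA-seq counts and photographic
    time series. Implements negative-binomial GLM differential expression
    under a batch + pair + condition design with median-of-ratios
    normalization and a regularized-log transform; Gene Ontology and
    pathway enrichment with annotation filtering, conditional
    hypergeometric tests and gene-set permutation nulls; developmental
    staging of samples against a reference time course via transcriptome
    distance profiles, penalized-spline models and finite-difference
    minima; and aggregate shape measurement, overlap-based tracking of
    split/merge events and mixed-effects models of shape and splitting.
    Synthetic-data generators with recorded ground truth make every stage
    testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    mgcv,
    nlme,
    tiff,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    DESeq2,
    Matrix
Config/testthat/edition: 3
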