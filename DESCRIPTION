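Package: ephysclust
Title: Unbiased Electrophysiological Classification of Spinal Interneurons
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Rule-based extraction of passive and active membrane properties
    from whole-cell patch-clamp recordings, firing-pattern taxonomy (tonic,
    initial doublet, initial burst, delayed), correlation-based feature
    reduction, principal component analysis, and dual unsupervised clustering
    (silhouette-elbow k-means and cophenetic-selected hierarchical clustering
    with inconsistency-coefficient cutting) for phenotyping adult spinal
    Shox2/Chx10 interneurons. Includes a synthetic-data generator that
    emulates the four firing archetypes at the trace level and per-cluster
    multivariate feature distributions, so every stage of the pipeline can
    be exercised and validated against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tools,
    stats,
    utils,
    jsonlite,
    withr
Suggests:
    testthat (>= 3.0.0),
    cluster,
    mclust,
    ape
Config/testthat/edition: 3
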