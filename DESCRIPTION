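Package: casaclust
Title: Motile Sperm Subpopulation Analysis from CASA Kinematics and
    Imaging Cytometry
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Two-step clustering (k-means followed by hierarchical
    agglomeration of centroids) of computer-assisted sperm analysis (CASA)
    kinematic descriptors into motile subpopulations, with cluster-number
    selection by silhouette average width, the Hubert Gamma coefficient and
    the L-method, and ten-fold subsample stability analysis. Companion
    modules provide imaging-flow-cytometry event gating (mitochondrial
    activity, viability, and regional tyrosine-phosphorylation
    quantification with baseline normalization), time-course and
    correlation statistics with compact-letter displays, and a fully
    parameterized synthetic-data generator with known ground truth for
    validating the whole pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    cluster,
    jsonlite,
    withr
Config/testthat/edition: 3
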