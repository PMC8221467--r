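Package: cranmorph
Title: Geometric Morphometric Ancestry Attribution from 3D Cranial Landmarks
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for 3D landmark-based geometric morphometrics of the
    cranial base, oriented towards population-ancestry attribution in
    skeletal bioarchaeology. Implements generalized Procrustes analysis,
    removal of bilateral (object) asymmetry by reflected relabelling,
    principal components and canonical variates ordination, stepwise
    cross-validated principal-component reduction, Wilks MANOVA with
    multivariate effect sizes, and two-source linear discriminant
    attribution with a posterior-probability threshold, together with a
    synthetic-study generator with known ground truth, an intra-observer
    error protocol, and readers and writers for common landmark file
    dialects (CSV, whitespace tables, TPS, Morphologika).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    yaml
Suggests:
    MASS,
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
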