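Package: exprdrift
Title: Distance-Based Classification and Prognosis from Whole-Transcriptome Profiles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Treats each sample's whole-transcriptome expression profile as a
    point in gene-expression space and classifies samples by their distances to
    subset centroids. Implements four distance metrics (Euclidean, per-gene
    scaled, uncentered Pearson/cosine, and Mahalanobis with pseudo-inverse or
    ridge regularization for singular covariance), naive and leave-one-out
    centroid profiles, barycentric/ternary coordinates for three-group distance
    profiles, group-separation tests, and a linear survival-versus-distance
    prognostic model. Includes a synthetic-cohort generator with tunable group
    drift and dispersion and survival linearly coupled to distance from the
    normal centroid, plus readers for tab-separated and GEO series-matrix
    expression tables and a reproducible end-to-end pipeline.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    MASS,
    stats,
    utils,
    tools,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
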