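Package: chromAge
Title: Imaging-Based Chromatin and Epigenetic Age from Nuclear Texture Features
Version: 0.9.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes an imaging-based chromatin/epigenetic age (ImAge) readout
    from multiplexed immunofluorescence images of cell nuclei. Band-pass
    threshold adjacency statistics (TAS) summarize nuclear texture per
    epigenetic mark; bootstrap-mean aggregation, z-scoring and repeated
    train/test splits construct an oriented young-to-old axis (centroid or
    linear SVM variants) whose projection coordinate is the age readout.
    Includes an information (variation-of-information) distance, Euclidean and
    hyperbolic (Lorentz-model) multidimensional scaling with embedding
    diagnostics, geodesic age readouts in hyperbolic space, age-related
    identity-erosion metrics (silhouette, Kolmogorov-Smirnov profiles),
    single-cell young/old signature calling, behavior-association analysis
    with constrained linear coefficients, and seeded synthetic-data generators
    for images, feature tables and behavior matrices.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    cluster,
    e1071,
    tiff,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
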