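Package: metaboPost
Title: Post-Processing, Annotation and Quality Control of LC-MS
    Metabolomics Feature Tables
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for curating LC-MS metabolomics feature tables after
    preprocessing: blank masking, outlier-sample removal by feature-count
    Z-score, one- and two-pass total-ion-current normalization with batch
    scaling, infrequent-feature removal, scalar-minimum imputation and
    ComBat batch correction. Degenerate features (isotopologues and
    adducts) are grouped into empirical compounds on a khipu-style
    isotope-adduct grid with inferred neutral mass, and annotated at
    Schymanski-style confidence levels: level 4 by neutral mass against
    compound databases, level 1b by m/z and retention time against
    authentic standards, and levels 2/1a by MS2 spectral similarity with
    interval-tree precursor indexing. Results are serialized as chainable
    empirical-compound JSON and a three-table export (features,
    annotations, metadata), with QC summaries and PDF reporting. A
    synthetic-experiment generator with planted ground truth supports
    end-to-end testing without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    graphics,
    jsonlite,
    S4Vectors,
    IRanges,
    SummarizedExperiment,
    igraph,
    ggplot2,
    pheatmap
Suggests:
    testthat (>= 3.0.0),
    withr,
    mzR,
    sva,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
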