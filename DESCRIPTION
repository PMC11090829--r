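Package: jsdfidelity
Title: Organoid Fidelity Scoring from Keratin Phenotype Distributions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies breast tissue and organoid heterogeneity from
    two-channel cytokeratin immunofluorescence. Section images are tiled,
    thresholded and reduced to K8+/K14+ areas; per-section log2(K8/K14)
    ratios are binned against quartiles of a normal-tissue reference; and
    any two conditions (starting tissue vs organoid, untreated vs treated)
    are compared with a normalized Jensen-Shannon divergence. Includes the
    minimum-section sample-size rule, marker-redundancy correlations,
    Mann-Whitney group comparisons, publication-style plots, and a fully
    seeded synthetic-data generator (images and section cohorts with known
    ground truth) for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    dplyr,
    ggplot2,
    jsonlite,
    png,
    rlang,
    stats,
    tibble,
    tiff,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
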