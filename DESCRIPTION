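Package: adipostrat
Title: Adiponectin Pathway Scoring and Stratification of Skin Transcriptomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Stratifies bulk skin-biopsy expression cohorts into
    adiponectin-pathway-low versus normal subsets. Derives a signed gene
    signature from a two-arm perturbation experiment, computes a
    control-standardized signed z-sum pathway activation score per sample,
    classifies samples against a control-derived confidence threshold,
    builds anchor-gene synexpression (co-expression) sets by Pearson
    correlation, clusters samples on them by correlation-distance average
    linkage, and quantifies disease enrichment in the reduced subset with
    2x2 odds-ratio, Woolf confidence-interval and chi-square/Fisher
    statistics. Includes seeded generators for synthetic perturbation
    datasets and biopsy cohorts with planted ground truth, so the whole
    pipeline is testable without any external accession.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    mclust,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
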