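Package: stereoquant
Title: Quantitative Proteomics Workflows for Stereocilia Membrane Enrichment
    and Bait Interactome Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Label-free and targeted mass-spectrometry analytics for
    subcellular enrichment and affinity-purification experiments on inner-ear
    stereocilia membranes. Implements relative iBAQ (riBAQ) quantitation with
    contaminant exclusion and isoform apportionment from isoform-unique
    peptides; purification-fraction enrichment-slope profiling with
    transmembrane-annotation rolling averages and Gaussian-mixture clustering
    of row-standardized profiles (BIC model selection); control-subtracted
    immunoaffinity enrichment statistics with empirical-Bayes moderated
    t-tests, Benjamini-Hochberg FDR and bait-relative stoichiometry; and
    parallel-reaction-monitoring (PRM) chromatogram quantitation with
    rule-based peak qualification, trapezoidal integration, bait-based
    experiment normalization and IP/total summaries. A seeded synthetic-data
    generator with known ground truth supports end-to-end testing of every
    stage without raw instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    pracma,
    yaml
Suggests:
    limma,
    mclust,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
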