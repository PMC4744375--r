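Package: oncoprofiler
Title: Offline Molecular Profiling of TCGA/Firehose-Style Cancer Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reads the four flat-file dialects distributed by the
    Broad Firehose pipeline for TCGA cohorts (MAF somatic mutation calls,
    GISTIC2.0 thresholded copy-number tables, RSEM-normalized expression
    matrices and Illumina 450k level-3 methylation beta values) and computes
    global and detailed molecular profiles across cancer entities: per-gene
    mutation frequencies with variant-class breakdowns, leave-one-out
    expression z-scores and fold changes with threshold calls, paired and
    unpaired Wilcoxon differential methylation with Benjamini-Hochberg
    correction and delta-beta quantification, and copy-number category
    summaries. A seeded synthetic-cohort generator emulates all four file
    dialects and the TCGA barcode grammar so every analysis is testable
    offline, and a batch command-line interface renders the standard figure
    types (profile grids, circle charts, waterfall, box, bar plots and
    delta-beta histograms) from the emitted tables.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
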