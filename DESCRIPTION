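Package: sdegtools
Title: Sex-Dependent Expression Analysis for Dioecious Floral Transcriptomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Downstream analysis toolkit for bulk RNA-seq studies of
    dioecious plants that contrast female and (super)male floral organs.
    Computes FPKM expression values from gene-level fragment counts,
    extracts sex-dependently expressed genes (SDEGs) with a thresholded
    fold-change rule, transfers GO and metabolic-pathway annotations
    through a one-to-one best-hit homolog map built from BLAST tabular
    output, tests term over- and under-representation with cumulative
    binomial probabilities against an FDR-derived significance level,
    compares SDEG sets with Jaccard indices, and runs correlation and
    hierarchical-clustering sample QC. A synthetic-data generator with
    planted ground truth makes the whole pipeline testable without any
    external download.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
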