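Package: tetrASE
Title: Haplotype-Quartet Allele-Specific Expression and Tissue-Enrichment
    Analysis for Autotetraploid Transcriptomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing allele-specific expression (ASE) in
    autotetraploid species whose genes are resolved into four haplotype
    copies (A-D). Builds 1:1:1:1 haplotype quartets from orthogroup tables,
    applies read-support filters, computes per-condition haplotype
    proportions, allelic-bias dominance classes, chi-square condition
    contrasts with Benjamini-Hochberg FDR, rank-switching calls and
    delta-max effect sizes. Also provides a negative-binomial GLM
    likelihood-ratio pipeline for tissue-enriched expression atlases and
    two-group stress differential expression, Fisher's exact term
    over-representation, and a Dirichlet-multinomial synthetic-data
    generator with recorded ground truth for calibration and power
    studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    MASS,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
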