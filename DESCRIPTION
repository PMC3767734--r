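Package: tfprogram
Title: Integrative Analysis of Transcription-Factor Regulatory Programs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Links a transcription factor to its downstream regulatory program by
    chaining promoter-motif target prediction (IUPAC consensus scanning around the
    transcription start site), gene set enrichment analysis with permutation nulls
    (from-scratch running-sum statistic, NES and FDR), leading-edge extraction and
    hypergeometric over-representation against curated collections, bisulfite
    amplicon CpG methylation calling with degenerate-primer validation, delta-delta-Ct
    relative transcript quantification with exact Mann-Whitney comparison, and exact
    2x2 contingency statistics (two-sided Fisher test, relative risk) for
    marker-versus-event cohorts. A synthetic-data module generates inputs with the
    statistical structure each stage assumes, so the whole pipeline is testable
    end-to-end without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    Biostrings,
    yaml
Suggests:
    testthat (>= 3.0.0),
    fgsea,
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
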