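Package: txmine
Title: Transcriptome Functional Mining: Co-Expression Networks,
    Expression Z-Scores, Cis-Element Enrichment and miRNA Target Rules
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A toolkit for mining functional information from plant
    transcriptome compendia. Summarizes replicated microarray intensities
    and read counts (RPKM), converts expression profiles to Z-scores for
    expression (ZFE) under an intensity/fold-change eligibility filter,
    builds mutual-rank (MR) gene co-expression networks with three-level
    ego-network expansion, tests promoter cis-elements for enrichment with
    a length-stratified resampling Z-score (ZFM), predicts plant miRNA
    targets with wobble-weighted complementarity rules and a duplex
    free-energy ratio criterion, and searches expression profiles by
    qualitative pattern or tissue specificity. Includes seeded synthetic
    data generators for all input types and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    withr,
    optparse,
    Biostrings
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
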