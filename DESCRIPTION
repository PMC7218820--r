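Package: hervcoex
Title: Provirus Co-Expression Screening and Preranked Gene Set Enrichment
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for testing which biological processes
    co-vary with the expression of a single designated feature (such as an
    endogenous retroviral provirus) in a two-group bulk RNA-seq study.
    Provides median-of-ratios count normalization, mean-expression and
    annotation prefilters, a per-group Pearson co-expression screen with
    t-based significance, a from-scratch preranked gene set enrichment
    analysis (running-sum enrichment scores, gene-permutation null,
    normalized enrichment scores, Benjamini-Hochberg and q-value FDR),
    and an exact hypergeometric test for over-representation of a term
    category among the top-ranked enriched terms.  A seeded synthetic-data
    generator produces two-group count matrices with planted group-specific
    co-expression so every stage can be validated against known truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    yaml
Suggests:
    testthat (>= 3.0.0),
    fgsea,
    DESeq2,
    optparse,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
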