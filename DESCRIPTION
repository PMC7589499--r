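Package: comboDE
Title: Consensus Differential Expression for Nested Replicate-Pooled RNA-Seq Designs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Differential-expression analysis for bulk RNA-seq experiments in
    which pooled biological replicates are nested within sites and sites within
    a two-level condition (e.g. anciently versus recently invaded populations).
    Implements three complementary strategies and their consensus: an exhaustive
    replicate-combination analysis that runs a negative-binomial conditional
    exact test on every possible selection of one replicate pool per site (the
    "4vs4" approach) with an 85% consensus rule; a nested fixed-factor
    negative-binomial generalized linear model over all libraries (the "8vs8"
    approach) tested by likelihood ratio; and a shared within-condition
    correlation model with empirical-Bayes moderated t-statistics. Includes
    relative-log-expression (RLE) normalization, low-count filtering,
    dispersion estimation with weighted-likelihood shrinkage,
    Benjamini-Hochberg correction, hypergeometric gene-set enrichment,
    Wilcoxon log-fold-change shift tests, and a negative-binomial count
    simulator reproducing the nested 2-condition/4-site/2-pool design for
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    edgeR,
    limma
Config/testthat/edition: 3
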