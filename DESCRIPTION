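Package: ervrates
Title: Context-Dependent Germline Mutation Rates from Extremely Rare Variants
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimation of context-dependent relative germline mutation rates
    from singleton (extremely rare) variants. Provides a canonical K-mer
    mutation-subtype taxonomy (K = 1, 3, 5, 7), sliding-window motif counting
    against a reference genome, per-subtype relative rate estimation with
    nested heterogeneity tests, per-sample 3-mer spectrum QC via rank-3
    non-negative matrix factorization, a likelihood framework that validates
    rate estimates against de novo mutations (AIC and Nagelkerke pseudo-R2),
    per-subtype logistic regression of mutability on local genomic features,
    and a genome-wide per-site predicted mutation-rate map with VCF
    annotation. A synthetic-data module generates reference sequences,
    feature tracks, singleton and de novo call sets with known ground truth
    so that every stage is testable end to end.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    jsonlite,
    stats,
    utils,
    methods
Suggests:
    testthat (>= 3.0.0),
    withr,
    vcfR,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
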