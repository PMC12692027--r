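Package: tadlink
Title: Enhancer-Promoter Association Analysis Within Topologically Associating Domains
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing the spatial association between enhancers and
    promoters constrained by topologically associating domains (TADs). Builds
    consensus TAD sets from two Hi-C-derived interval tracks (interval merge,
    intersection and Jaccard statistics), enumerates candidate
    enhancer-promoter pairs by linear proximity and TAD co-localisation,
    filters them by two-condition differential expression, quantifies the
    four sign-pattern interaction classes per tissue, and tests the
    association between TAD-aggregated enhancer and promoter expression with
    a battery of correlation and regression statistics (Pearson, Spearman,
    Kendall tau-b, least squares, Theil-Sen) against an adjacent-TAD shifted
    null. A synthetic-data generator with known ground truth (shared per-TAD
    activity, feature-level noise, configurable differential-expression sign
    mixtures) makes every stage testable without external sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    GenomeInfoDb,
    graphics,
    methods,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
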