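Package: notchcaller
Title: NOTCH Pathway Activation Calling and Preclinical Efficacy Statistics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Transcriptome-based calling of NOTCH pathway activation from
    bulk expression profiles, combining a single-sample gene-set enrichment
    (ssGSEA) running-sum score with a k-Top-Scoring-Pairs (kTSP) rank score
    over curated up- and down-regulated NOTCH target gene sets. Supporting
    stages cover median-of-ratios count normalization, a moment-based
    negative-binomial Wald test with the three-filter differential-expression
    rule (mean > 50 normalized reads, |log2 fold-change| > 1, FDR < 0.05),
    minimal-hypergeometric ranked-list enrichment with exact permutation
    p-values, exact binomial overlap tests, Ward.D2 signature clustering,
    xenograft efficacy statistics (caliper tumor volumes, percent tumor
    growth inhibition, per-animal log-linear growth rates with ANOVA and
    Tukey-Kramer comparisons), qPCR 2^-ddCt fold changes, and
    negative-binomial synthetic-data generators for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
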