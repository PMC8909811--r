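Package: heteroseq
Title: Expression-Level Dominance and Heterosis Analysis for Hybrid RNA-Seq Designs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis of hybrid-vigor (heterosis) expression patterns in a
    two-parent/hybrid RNA-seq design: TPM quantification, median-of-ratios size
    factors, a negative-binomial Wald test for pairwise stock contrasts and for
    the hybrid-versus-mid-parent (non-additivity) contrast, classification of
    features into the twelve additivity / expression-level dominance /
    overdominance categories, construction of negative miRNA-mRNA interaction
    networks, hypergeometric pathway over-representation, and growth-trait
    metrics.  Includes a seeded negative-binomial simulator with known
    ground-truth expression patterns for end-to-end validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, tools, jsonlite, grDevices, graphics
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
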