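Package: dormsig
Title: Dormancy Signature Scoring and Co-Expression Analysis for Melanoma Transcriptomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to quantify a dormancy-proliferation axis in melanoma
    expression data. Implements an eight-gene composite dormancy score on
    z-scored log2(TPM+1) values, rank-based differential-expression filtering
    with PCA-driven signature derivation, a self-contained weighted
    co-expression network analysis (soft-threshold adjacency, topological
    overlap, static-cut module detection, eigengenes, hub genes), DNA-versus-RNA
    variant allele fraction concordance tabulation, Kaplan-Meier / log-rank
    survival stratification and chi-square response testing, plus a seeded
    synthetic cohort generator that plants every structure the pipeline is
    expected to recover.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    pROC,
    survival,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
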