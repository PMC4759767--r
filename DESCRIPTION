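Package: coxen
Title: Co-Expression Extrapolation Models of Drug Response Across Species
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds and validates interspecies chemosensitivity prediction
    models from gene-expression panels using the co-expression extrapolation
    (COXEN) strategy: within-gene standardization, differential expression
    between drug-sensitivity extremes (SAM or t-test), cross-platform probeset
    matching (sequence homology, correlative match, or collapse-to-gene),
    filtering of the signature to genes whose co-expression structure is
    conserved in a target-like panel, misclassification-penalized-posterior
    (MiPP) forward model selection with linear discriminant analysis, and
    clinical-outcome evaluation (binomial accuracy tests, Kaplan-Meier /
    log-rank comparisons, proportional-hazards modeling). Includes a synthetic
    paired-species panel generator with planted, partially conserved
    drug-sensitivity signal so the whole pipeline is testable without
    external microarray data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    MASS,
    survival,
    jsonlite,
    Biostrings
Suggests:
    e1071,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
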