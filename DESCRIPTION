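Package: pleiotree
Title: Pleiotropy-Informed SNP Prioritization with Functional Annotation Trees
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Joint prioritization of SNPs associated with one or both of two
    GWAS traits by integrating association p-values with binary functional
    annotations. A four-state Beta-Uniform mixture model is fitted with a
    two-stage EM algorithm whose second-stage M-step is a multivariate
    regression tree over the annotations, so that the fitted tree exposes the
    combinations of functional annotations that characterize risk-associated
    SNPs. Per-SNP local false discovery rates for marginal and joint
    associations are computed from the posterior state probabilities and the
    global false discovery rate is controlled by the direct posterior
    probability approach. Includes a simulation engine for power, FDR and
    annotation-selection studies.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    pROC
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
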