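Package: dietseq
Title: Diet-Responsive Transcriptome Analysis with Shared-Reference
    Concordance Testing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for bulk RNA-seq experiments contrasting
    dietary treatments across tissues, modelled on a three-diet by
    three-tissue factorial design in outbred Drosophila. Provides a
    negative-binomial simulator with planted ground truth, median-of-ratios
    normalization and filtering, surrogate-variable and batch-effect
    correction, nested-model likelihood-ratio differential expression with
    moderated log2 fold changes, a constrained-permutation test for the
    concordance of fold changes computed against a shared reference diet,
    signed weighted co-expression network module detection with
    resampling-based membership robustness and eigengene ANOVA, and
    set-level enrichment statistics (two-sample t and Fisher exact) for
    GMT gene-set collections.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    limma,
    MASS,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils
Suggests:
    mclust,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
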