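Package: iciomics
Title: Multi-Omics Biomarker Modelling of Anti-PD1 Response in Melanoma
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Derives 40 genomic and 9 transcriptomic biomarkers from
    upstream somatic-variant, copy-number, neoantigen, HLA, clonotype and
    expression call files; trains a cascaded DNA/RNA/multi-omics LASSO
    model with permutation-importance feature gating and Youden
    thresholding; evaluates against the nonsynonymous tumor mutation
    burden baseline; and explains per-sample predictions with exact
    linear SHAP values. Ships a synthetic cohort generator with known
    ground truth so the full analysis is testable without
    controlled-access data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    tools,
    glmnet,
    GenomicRanges,
    IRanges,
    sva
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
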