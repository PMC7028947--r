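Package: icipredict
Title: Clinico-Genomic Prediction of Benefit from PD-1/PD-L1 Blockade in
    Metastatic Urothelial Carcinoma
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An integrated analysis pipeline for panel-sequenced metastatic
    urothelial carcinoma cohorts treated with immune checkpoint inhibitors:
    putative-germline variant triage and SNV (tumour mutational burden)
    counting, 96-channel trinucleotide spectra with non-negative
    least-squares projection onto bladder-cancer mutational signatures,
    copy-number event counting restricted to tumour-suppressor deletions and
    oncogene amplifications, DNA damage repair (DDR) alteration calls under
    inclusive and restrictive criteria, exact and rank-based univariable
    association tests, adaptive-LASSO variable selection with
    backward-eliminated multivariable logistic and Cox models, and a
    three-factor clinical point score (visceral metastasis, NLR >= 5, SNV
    count >= 10) with risk-group prognostic indices. A synthetic cohort
    simulator with a null comparator arm supports end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    glmnet,
    survival,
    pracma,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
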