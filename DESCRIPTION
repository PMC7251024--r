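Package: vivoseq
Title: Calcium-Response Classification and Quality Control for Vivo-Seq
    Single-Neuron Transcriptomics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for combined in vivo calcium imaging and
    single-neuron RNA sequencing ("vivo-seq") of visual cortex. Classifies
    neurons as light-sensitive or non-light-sensitive from stimulus-locked
    dF/F calcium responses, applies staged single-cell quality control with
    FPKM normalization and multiplicative marker-gene doublet scores, performs
    two-group differential expression with Benjamini-Hochberg correction, runs
    a simplified weighted co-expression module analysis with module
    eigengene-trait correlation, and compares curated ion-channel and receptor
    gene panels between groups. Includes a synthetic-data module that
    generates calcium-trace and expression cohorts with planted ground truth.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    Matrix,
    stats,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
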