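Package: pioneerbind
Title: Pioneer-Factor Binding-Site Classification and Motif-Affinity Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for dissecting ectopic pioneer transcription-factor activity
    from peak-level genomics data: classification of binding sites by prior
    chromatin accessibility and opening, derivation of co-bound sites and their
    pioneered/cooperative taxonomy, activation calls on RNA-seq counts with
    cumulative hypergeometric tissue enrichment, FIMO-style position weight
    matrix scanning with exact score-null p-values, and an aggregate
    motif-affinity score evaluated with threshold-sweep ROC curves. Includes a
    synthetic-data generator that plants motif instances, peak sets, and
    negative-binomial counts with known ground truth so the whole pipeline can
    be validated end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    BiocGenerics,
    Biostrings,
    IRanges,
    S4Vectors,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    DESeq2,
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
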