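Package: crmscreen
Title: Prediction and Reporter-Assay Validation of Muscle Cis-Regulatory Modules
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for predicting candidate skeletal-muscle cis-regulatory
    modules (CRMs) from clusters of transcription factor binding sites and for
    analysing dual-luciferase reporter screens that validate them. Includes
    position weight matrix scanning with relative-score thresholds, sliding
    window logistic-regression and additive cluster scoring of candidate
    modules, quality control and consensus calling for firefly/renilla plate
    data with a moderated differential statistic and permutation false
    discovery rate, sequence composition and conservation summaries,
    phylogenetic-depth analysis of binding sites, Fisher exact motif
    over-representation and ChIP-seq peak overlap statistics, ROC evaluation,
    and a fully seeded synthetic-data generator that emulates every input so
    the whole pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
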