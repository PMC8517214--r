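Package: tfdynamics
Title: Temporal Deconvolution of Transcription Factor Activity from
    Nascent Transcription and Chromatin Accessibility
Version: 0.1.0
Authors@R:
    person("Repo", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: An integrated pipeline for dissecting multiplexed
    transcriptional responses to a heterogeneous exposure measured at
    several time points. Detects origins of bidirectional (eRNA)
    transcription from strand-specific nascent-transcription reads, ranks
    genes and regulatory regions by differential activity with a
    negative-binomial model, classifies responses into early-peak,
    early-plateau and late temporal clusters, calls accessibility peaks
    against a local Poisson background, and identifies candidate driver
    transcription factors through motif-displacement enrichment around
    region centers using exact PWM score-distribution thresholds. A
    synthetic-data module generates every input with known ground truth
    so the whole pipeline can be validated without external downloads.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    stats,
    utils,
    tools,
    methods,
    Rcpp,
    Biostrings
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
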