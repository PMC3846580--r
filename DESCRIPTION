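Package: dhscreen
Title: Screening Gene- and Cell-Type-Specific Enhancers from DNase I
    Hypersensitive Site Panels
Version: 1.0.0
Authors@R: person("Qian", "Developer", role = c("aut", "cre"),
    email = "maintainer@dhscreen.dev")
Description: An end-to-end screen for gene- and cell-type-specific
    enhancers starting from multi-cell-type DNase I hypersensitive site
    (DHS) peak panels. Classifies DHSs within a gene locus domain as
    cell-type specific, putatively specific or non-specific; nominates
    candidate genes by RPKM up-regulation and delta-delta-Ct qPCR;
    scores dual-luciferase reporter plates against minimal-promoter and
    gene-promoter baselines with fold-threshold and ANOVA enhancer
    calls; joins conservation, FAIRE, histone-mark and transcription
    factor ChIP evidence; and summarizes the screen as a cross
    tabulation with k-means classes of TF occupancy scores. Ships a
    synthetic-data generator with planted ground truth so every stage
    is testable without external downloads.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    optparse
Suggests:
    testthat (>= 3.0.0),
    yaml,
    IRanges
Config/testthat/edition: 3
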