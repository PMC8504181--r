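Package: nucshift
Title: Activity-Dependent Nuclear Proteome and Transcriptome Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for linking neuronal stimulation to nuclear proteome and
    transcriptome changes. Implements tandem-mass-tag (TMT) reporter-ion
    summarization by two-way median polish with reference-channel run
    normalization and the two-stage enrichment gates used in nucleus-targeted
    proximity-labeling proteomics; stratified negative-binomial Wald
    differential expression with replicate-batch correction; the PDCD4
    change-index cascade that classifies activity-dependent,
    cycloheximide-insensitive and putative PDCD4 target genes; auxiliary
    quantification statistics (per-cell intensity normalization, Western
    ratio normalization, qPCR relative expression, exact Mann-Whitney U with
    Bonferroni correction); and seeded synthetic-data generators with planted
    truth labels for end-to-end recovery evaluation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
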