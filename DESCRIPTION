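Package: glistat
Title: Cooperative GLI/STAT Pathway Activity and IDO1 Synergy Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Tools for quantifying cooperative Hedgehog/GLI and JAK/STAT
    signaling driving IDO1 expression in skin cancer transcriptomes.
    Implements trimmed-mean-of-M-values (TMM) scaling and log2
    counts-per-million transformation of bulk RNA-seq counts, gene-set
    pathway-activity scoring with high/low stratification, an interaction
    (synergy) linear model for a target gene, single-cell GLI/STAT1
    co-activity classification with Fisher's exact enrichment test, the
    supporting assay arithmetic (delta-delta-Ct, factorial synergy score,
    ChIP percent-of-input, internal-standard metabolite ratios), and a
    seeded synthetic-data generator that plants known effects so every
    pipeline stage can be validated without access to patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Matrix,
    jsonlite,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    edgeR,
    limma
Config/testthat/edition: 3
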