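Package: lncImmPath
Title: Identify lncRNA Modulators of Immune-Related Pathways from Tumor
    Expression Profiles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Identifies candidate long noncoding RNA (lncRNA) modulators of
    immune-related pathways from sample-matched lncRNA and mRNA expression
    profiles of tumor cohorts. For every lncRNA, coding genes are ranked by a
    signed rank score derived from the tumor-purity-adjusted partial
    correlation, pathways are scored with a weighted Kolmogorov-Smirnov
    enrichment statistic and an analytic tail p-value, and significance is
    rescaled to a bounded pathway-regulation score (lncRES). Per-pathway
    recurrence across cohorts, together with tumor-versus-normal expression
    perturbation, is aggregated into a normalized-rank priority score for
    intergenic lncRNAs. A Spearman filter against immune-cell infiltration
    estimates and a synthetic-cohort generator with planted regulators,
    purity confounders and perturbed transcripts are included for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
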