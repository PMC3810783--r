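Package: longevomics
Title: Lifespan and Liver Transcriptome Analysis for Longevity Interventions
Version: 0.9.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: An integrated analysis toolkit for studies of lifespan-extending
    interventions in rodent cohorts. Provides Kaplan-Meier lifespan summaries,
    log-rank contrasts and the Wang/Allison maximal-lifespan quantile test;
    empirical-Bayes moderated-t differential expression with detection
    filtering, sibling-probe collapse and fold-change classification;
    rank-based (Wilcoxon) cross-experiment gene-set concordance screens;
    conditional hypergeometric term overrepresentation on an ontology DAG;
    position-weight-matrix scanning of masked upstream regions with
    semiparametric generalized-additive logistic motif enrichment; and small
    closed-form phenotype calculators (HOMA-IR, respiratory quotient,
    delta-delta-Ct fold induction). A seeded synthetic-data module generates
    every input with planted ground truth so the full pipeline can be
    exercised and power-checked end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    splines,
    survival,
    flexsurv,
    igraph,
    jsonlite,
    S4Vectors,
    SummarizedExperiment,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    limma,
    mgcv
Config/testthat/edition: 3
RoxygenNote: 7.3.3
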