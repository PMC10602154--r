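Package: regdomains
Title: Cis- and Trans-Regulatory Domain Analysis of Population-Scale
    Chromatin Accessibility
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Analysis of population-scale ATAC-seq chromatin accessibility:
    case/control differential open-chromatin regions (OCRs) with covariate
    adjustment, assembly of cis-regulatory domains (CRDs) from
    inter-individual correlation along chromosomes, a two-stage
    differential-CRD test with false-discovery-rate control, discovery of
    trans-regulatory domains (TRDs) by hierarchical clustering with
    Goodman-Kruskal Gamma model selection, per-sample disease staging by
    diffusion pseudotime, set-enrichment z-scores in single-cell ATAC with a
    donor-random-effect cell-type test, and interval-restricted polygenic
    scoring stratified by TRD. Includes a synthetic-data generator that
    plants recoverable domain structure, disease effects, and genetic
    liability so the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    methods,
    Matrix,
    igraph,
    lme4,
    sandwich,
    GenomicRanges,
    IRanges,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    limma,
    mclust,
    withr,
    yaml
Config/testthat/edition: 3
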