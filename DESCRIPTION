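Package: sexscreen
Title: Consensus Screening, Literature Mining and Validation Statistics for
    Sex-Biased Gene Expression
Version: 0.99.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: A data-driven candidate-gene discovery pipeline for sex-biased
    gene expression in peripheral blood. Reads GEO series-matrix expression
    data, computes empirical-Bayes moderated t contrasts between female and
    male samples, applies a three-dataset consensus filter, mines abstract
    corpora for gene mentions with an HGNC-derived dictionary matcher,
    integrates and ranks candidates, tests gene-set overlap, performs qBase
    multi-reference qPCR quantification, and provides the exact Mann-Whitney,
    Spearman and Benjamini-Hochberg machinery used to validate candidates in
    clinical cohorts. A synthetic-data module with known ground truth
    emulates every input so the full pipeline runs and is tested offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    SummarizedExperiment,
    yaml
Suggests:
    testthat (>= 3.0.0),
    limma,
    fgsea,
    jsonlite
Config/testthat/edition: 3
biocViews: Transcriptomics, DifferentialExpression, TextMining, qPCR
RoxygenNote: 7.3.3
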