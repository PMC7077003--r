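Package: dmsbench
Title: Benchmarking Variant Effect Predictions Against Deep Mutational Scanning
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for comparing deep mutational scanning (DMS) effect
    measurements with variant effect predictions. Raw per-variant assay
    scores are anchored at the wild-type score, oriented so that larger
    values denote stronger effect, and interpolated per measurement and per
    effect side (deleterious or beneficial) onto the unit interval.
    Synonymous variants provide an empirical null from which neutral/effect
    classifications are derived (middle 90/95/99 percent schemes). Predictor
    score files are harmonized onto the same unit scale from each method's
    theoretical score range, with a naive conservation baseline read off
    PSI-BLAST position-specific scoring matrices and shuffled-score and
    Gaussian null baselines. Evaluation covers Spearman and Pearson
    correlation and mean squared error with percentile-bootstrap confidence
    intervals, ROC/AUC and precision-recall on the synonymous-derived
    labels, recall binned by effect strength, and inter-experiment agreement
    statistics. A synthetic-data module generates DMS-like score sets,
    replicate experiments and predictors at controlled rank correlations,
    and matching PSSM profiles, so the full pipeline is testable without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    optparse
Config/testthat/edition: 3
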