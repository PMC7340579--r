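Package: pdbqual
Title: Composite Quality Scores and Temporal Percentile Ranking of
    Crystallographic PDB Deposits
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for assessing the quality of X-ray crystallographic
    models deposited in the Protein Data Bank from their validation
    metrics (Clashscore, Ramachandran and Rotamer outliers, RSRZ
    outliers, R-free). Provides tie-averaged percentile ranking,
    a PCA-based geometry aggregate, the composite scores Q1p and Q1n
    with averaging and minimum variants, and time- and
    resolution-conditioned quality percentiles that rank every deposit
    against the archive as it stood at deposition time. Includes
    chained-equations imputation of missing metrics with a masking-based
    evaluation harness (MAD/MAE/RMSE, Friedman and Nemenyi tests),
    journal-level quality rankings with Welch tests, windowed rankings,
    bibliometric (IPP/SNIP) correlation analysis, and a synthetic deposit
    generator for testing the full pipeline without archive downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    readr,
    rlang,
    stats,
    utils,
    tools,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
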