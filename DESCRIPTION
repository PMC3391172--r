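Package: msci
Title: Replicate Quality, Variance Decomposition and X-Chromosome
    Enrichment Analysis for Developing-Testis Expression Data
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for re-analysing developing-testis microarray time
    courses and tissue expression panels in Drosophila, with a focus on
    meiotic sex chromosome inactivation (MSCI). Provides replicate-quality
    diagnostics (pairwise replicate correlations), a sum-of-squares
    variance decomposition separating among-gene signal from
    within-replicate experimental error, per-stage X-versus-autosome
    expression contrasts, tissue-specificity and testis/ovary sex-bias
    classification from expression atlas panels, and chromosomal
    enrichment statistics (Fisher exact or Yates-corrected chi-square by
    sample size, normalized X-linked frequencies with standard-error
    bands) including re-testing after removal of sex-biased genes. A
    synthetic-data generator produces replicate matrices and tissue
    panels with known ground truth so every stage of the pipeline can be
    validated without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    knitr
Config/testthat/edition: 3
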