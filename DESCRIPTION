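Package: editscape
Title: Differential A-to-I RNA Editing Analysis for Drug-Resistance Pharmacogenomics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for relating A-to-I RNA editing to anticancer drug response:
    differential editing-site (DES) calling between resistant and sensitive
    samples (Wilcoxon rank-sum test, p < 0.05 and |Diff| >= 5%), overall
    editing level (OEL) summaries and ADAR-expression regressions,
    hypergeometric enrichment of DESs in transcribed regions and within genes
    (gene-specific changing background), Meet/Min (Simpson) overlap of DES
    sets across conditions, survival association of editing levels (median
    binarization, univariate Cox regression, log-rank test) with a
    resistance-consistency score, and an editing-aware microRNA regulation
    screen on 3'-UTRs (canonical seed-site gain/loss under A-to-G editing
    plus expression-level triplet filters). Includes a synthetic-data
    generator with known ground truth so every stage can be exercised and
    validated without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    survival,
    Biostrings,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
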