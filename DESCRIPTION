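Package: episeq
Title: Cross-Perturbation Transcriptome Comparison Statistics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Downstream statistical machinery for comparing the transcriptomes of
    two perturbations (e.g. knockouts of an upstream regulator and its downstream
    effector): cell-cycle-phase percentile-rank enrichment against the genome-wide
    median, regulated-gene-set definitions and one-tailed hypergeometric overlap
    tests, cross-dataset Spearman concordance with a bootstrap null built from
    random gene sets, an attenuation-slope linear model of log2 fold changes, and
    chi-squared homogeneity statistics for proliferation (EdU) counts.  Includes a
    seeded synthetic-data generator that emulates differential-expression summary
    tables with a planted attenuation coefficient, so every stage is verifiable by
    oracle equivalence and parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    graphics,
    jsonlite,
    yaml,
    fgsea
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
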