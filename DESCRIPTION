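Package: tritier
Title: Three-Tiered Integrative Transcriptomics for Multi-Aetiology Disease Compendia
Version: 0.1.0
Authors@R:
    person("Repo", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Integrative analysis of multi-dataset expression compendia in three
    tiers: per-comparison rank-product differential expression with
    permutation-based pfp estimates, per-sample pre-ranked gene set enrichment
    (weighted Kolmogorov-Smirnov running-sum statistic with gene-permutation
    nominal p-values) with frequency consensus across samples and conditions,
    and transcription-factor-to-pathway regulatory screening via one-sided
    Fisher's exact tests. Includes a synthetic-compendium generator with a
    ground-truth manifest (planted frequently differentially expressed genes,
    planted pathway shifts, planted regulatory couplings) for end-to-end
    recovery benchmarking, a random-forest signature evaluator with pooled
    out-of-fold ROC AUC, and readers/writers for tab-separated expression
    matrices, sample sheets, GMT gene set collections and regulatory edge
    lists.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
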