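Package: etiohet
Title: Supervised Discovery of Etiologically Distinct Tumor Subtypes
Version: 0.1.0
Authors@R:
    person("Repo", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for identifying disease subtypes that differ in their
    risk-factor profiles (etiologic heterogeneity). Candidate partitions of
    cases are generated by restarted k-means clustering of genomic feature
    matrices (expression, methylation, copy-number segment means); each
    partition is scored with a case-only heterogeneity statistic D* derived
    from polytomous logistic regression of subtype membership on risk
    factors, and the partition maximizing D* is selected. Permutation tests
    assess the presence of heterogeneity and the incremental value of
    additional subtypes. Post-hoc analyses include risk-profile tables,
    mutation associations, cross-platform subtype congruence, competitive
    rank-based gene-set enrichment, and survival summaries. A synthetic-data
    module generates populations with planted subtype structure for
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    survival,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
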